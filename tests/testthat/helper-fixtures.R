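# shared fixtures, all generated in code

toy_truth <- function() c(rest = 1.12, amp = 0.9, apd = 1.25, rst = 0.75)

toy_baselines <- function(pcls = c(300, 1000), mode = "absolute",
                          truth = toy_truth(), snr_db = Inf, seed = NULL) {
  traces <- lapply(pcls, function(p) {
    tr <- toy_ap(toy_reference() * truth, p)
    if (is.finite(snr_db))
      tr <- add_noise(tr, snr_db, seed = if (is.null(seed)) NULL else seed + p)
    tr
  })
  baseline_set(traces, mode = mode)
}

# rectangular-ish pulse trace: rest at -85, plateau at +30 for `width` ms
square_ap <- function(width = 100, pcl = 500, rest = -85, peak = 30) {
  t <- seq(0, pcl - 1)
  v <- ifelse(t >= 10 & t < 10 + width, peak, rest)
  ap_trace(t, v, pcl = pcl)
}

# two printed initial-concentration states for the multiple-steady-state runs
fig2_state <- function(which) {
  st <- ord_initial_state()
  if (which == 1) {
    st[["ki"]] <- 145; st[["kss"]] <- 145
    st[["nai"]] <- 5; st[["nass"]] <- 5
    st[["cansr"]] <- 0.5
  } else {
    st[["ki"]] <- 120; st[["kss"]] <- 120
    st[["nai"]] <- 8; st[["nass"]] <- 8
    st[["cansr"]] <- 4
  }
  st
}

expression_fixture <- function() {
  genes <- names(gene_parameter_map())
  m <- cbind(P1 = seq(10, 130, by = 10), P2 = seq(10, 130, by = 10))
  rownames(m) <- genes
  m
}
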