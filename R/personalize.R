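#' Default gene-to-parameter map
#'
#' Each scaled model parameter is represented by the mRNA of the
#' pore-forming (or catalytic) subunit of the corresponding channel, pump
#' or buffer.
#' @return named character vector, gene symbol -> parameter name.
#' @export
gene_parameter_map <- function() {
  c(SCN5A = "gNa", KCNH2 = "gKr", KCNJ2 = "gK1", KCNQ1 = "gKs",
    CACNA1C = "PCaL", KCNA4 = "gto", ATP1A1 = "gNaK", SLC8A1 = "gNCX",
    ATP2B4 = "gpCa", RYR2 = "Jrel", ATP2A2 = "Jup", CALM1 = "CMDN",
    CAMK2D = "CaMKII")
}

#' Generate synthetic steady-state baselines from known parameters
#'
#' Paces the ionic model with the given (hidden-truth) scaling to steady
#' state at each PCL, optionally corrupts the last beat with Gaussian noise
#' at a stated SNR, and optionally strips the absolute scale (min-max
#' normalization) to emulate optical recordings. The truth (scaling plus
#' reached slow concentrations) is attached for later scoring.
#'
#' @param scaling true [scaling_factors()].
#' @param pcls pacing cycle lengths (ms).
#' @param settle_s pacing time per PCL (s).
#' @param snr_db noise level (dB); `Inf` for noiseless.
#' @param seed integer seed for the noise.
#' @param mode `"optical"` (normalized traces, renormalizing fitness) or
#'   `"absolute"`.
#' @param dt_max integrator step cap (ms).
#' @param weights per-PCL fitness weights.
#' @return a [baseline_set()] with attribute `"truth"`: list(`scaling`,
#'   `nai`, `cansr`, `final_states`). Non-capturing PCLs (no AP on the last
#'   beat) are dropped with a warning.
#' @export
make_baselines <- function(scaling = scaling_factors(), pcls,
                           settle_s = 1000, snr_db = Inf, seed = NULL,
                           mode = c("optical", "absolute"), dt_max = 1,
                           weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(!anyDuplicated(pcls))
  traces <- list()
  nai <- cansr <- numeric()
  finals <- list()
  kept <- numeric()
  for (pcl in pcls) {
    res <- pace_to_steady_state(scaling, pcl = pcl, settle_s = settle_s,
                                dt_max = dt_max)
    ok <- res$ok && diff(range(res$trace$v)) >= 30
    if (!ok) {
      warning("PCL ", pcl, " ms does not capture 1:1; dropped", call. = FALSE)
      next
    }
    tr <- res$trace
    if (is.finite(snr_db))
      tr <- add_noise(tr, snr_db,
                      seed = if (is.null(seed)) NULL else seed + round(pcl))
    if (mode == "optical") {
      v <- (tr$v - min(tr$v)) / diff(range(tr$v))
      tr <- ap_trace(tr$time, v, pcl = pcl, normalized = TRUE)
    }
    traces[[length(traces) + 1]] <- tr
    kept <- c(kept, pcl)
    nai <- c(nai, res$final_state[["nai"]])
    cansr <- c(cansr, res$final_state[["cansr"]])
    finals[[length(finals) + 1]] <- res$final_state
  }
  if (!length(traces)) stop("no capturing PCL")
  bs <- baseline_set(traces, weights = weights, mode = mode)
  attr(bs, "truth") <- list(scaling = as_scaling(scaling),
                            nai = stats::setNames(nai, kept),
                            cansr = stats::setNames(cansr, kept),
                            final_states = finals)
  bs
}

#' Steady-state APD restitution curve
#'
#' Steady action-potential duration per pacing cycle length.
#'
#' @param scaling [scaling_factors()].
#' @param pcls pacing cycle lengths (ms).
#' @param settle_s pacing time per PCL (s).
#' @param level repolarization level (percent).
#' @param dt_max integrator step cap (ms).
#' @return data.frame with `pcl` and `apd` (ms; `NA` for non-capturing PCLs).
#' @export
restitution_curve <- function(scaling = scaling_factors(), pcls,
                              settle_s = 100, level = 90, dt_max = 1) {
  apd <- vapply(pcls, function(pcl) {
    res <- pace_to_steady_state(scaling, pcl = pcl, settle_s = settle_s,
                                dt_max = dt_max)
    if (!res$ok) return(NA_real_)
    ap_biomarkers(res$trace, level = level)$apd
  }, numeric(1))
  data.frame(pcl = pcls, apd = apd)
}

#' Read a gene-expression table
#'
#' TSV with gene symbols in the first column and one column of normalized
#' expression (TPM or normalized counts) per sample. One row per gene;
#' multi-promoter aggregation is the caller's responsibility.
#'
#' @param path TSV file path.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative expression values")
  m
}

#' Rescale fitted parameters by mRNA expression ratios
#'
#' Produces a second subject's model from a fitted genome under the
#' assumption that each conductance is proportional to the expression of
#' its pore-forming subunit: every multiplier is multiplied by the
#' target/reference expression ratio of its mapped gene. Slow-variable
#' genes are dropped (the new subject's concentrations must re-equilibrate
#' by pacing). Rescaled multipliers may leave the optimizer's search range;
#' they are clipped only to the optional model-validity `limits`.
#'
#' @param fitted fitted genome (named vector containing the 13 multipliers)
#'   or a [scaling_factors()] vector.
#' @param expr genes x samples expression matrix ([read_expression_table()]).
#' @param reference,target sample (column) names.
#' @param map gene -> parameter map ([gene_parameter_map()]).
#' @param limits optional `c(lower, upper)` validity bounds; `NULL` (the
#'   default) applies none.
#' @return [scaling_factors()] vector (unchecked against the search range).
#' @export
rescale_by_expression <- function(fitted, expr, reference, target,
                                  map = gene_parameter_map(), limits = NULL) {
  stopifnot(all(c(reference, target) %in% colnames(expr)))
  missing_genes <- setdiff(names(map), rownames(expr))
  if (length(missing_genes))
    stop("expression table lacks gene(s): ",
         paste(missing_genes, collapse = ", "))
  s <- unclass(fitted)[scaling_names()]
  if (anyNA(s)) stop("fitted genome lacks some scaling multipliers")
  for (gene in names(map)) {
    ref_val <- expr[gene, reference]
    if (!is.finite(ref_val) || ref_val <= 0)
      stop("zero or missing reference expression for gene ", gene)
    s[[map[[gene]]]] <- s[[map[[gene]]]] * expr[gene, target] / ref_val
  }
  if (!is.null(limits)) {
    if (any(s < limits[1]) || any(s > limits[2]))
      warning("rescaled multipliers clipped to validity limits")
    s <- clamp(s, limits[1], limits[2])
  }
  structure(s, class = "scaling_factors")
}
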