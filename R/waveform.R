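#' Uniformly sampled action-potential trace
#'
#' @param time sample times (ms), uniformly spaced, >= 50 samples for
#'   downstream metrics (shorter traces are allowed but most operations
#'   will refuse them).
#' @param v potential samples (mV, or arbitrary units for optical input).
#' @param pcl pacing cycle length label (ms).
#' @param normalized `TRUE` for optical-style traces without absolute scale.
#' @return list of class `"ap_trace"`.
#' @export
ap_trace <- function(time, v, pcl = NA_real_, normalized = FALSE) {
  stopifnot(length(time) == length(v), length(time) >= 2)
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * max(dt))
    stop("ap_trace requires uniform sampling")
  structure(list(time = as.numeric(time), v = as.numeric(v),
                 pcl = as.numeric(pcl), normalized = isTRUE(normalized)),
            class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("<ap_trace> %d samples @ %.3g ms, PCL %s ms, range [%.4g, %.4g]%s\n",
              length(x$time), x$time[2] - x$time[1],
              format(x$pcl), min(x$v), max(x$v),
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

trace_dt <- function(tr) tr$time[2] - tr$time[1]

#' Sub-sample time of the half-maximum upstroke crossing
#'
#' First upward crossing of the half-amplitude level, located by linear
#' interpolation between samples.
#' @param tr an [ap_trace()].
#' @return time (ms), or `NA` when the trace has no upstroke.
#' @export
half_max_time <- function(tr) {
  rng <- range(tr$v)
  if (diff(rng) <= 0) return(NA_real_)
  level <- rng[1] + diff(rng) / 2
  below <- tr$v < level
  idx <- which(below[-length(below)] & !below[-1])
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  frac <- (level - tr$v[i]) / (tr$v[i + 1] - tr$v[i])
  tr$time[i] + frac * (tr$time[i + 1] - tr$time[i])
}

#' Align two traces on their half-maximum depolarization
#'
#' The half-maximum upstroke crossing of each trace is used as the common
#' reference point; the candidate is resampled (linear interpolation) onto
#' the reference grid over the overlapping support.
#'
#' @param reference,candidate [ap_trace()] objects containing an upstroke.
#' @return list: `shift` (ms to add to candidate times), `reference` and
#'   `candidate` (on the common grid), `ok` (`FALSE` when either trace has
#'   no upstroke crossing).
#' @export
align_half_max <- function(reference, candidate) {
  t_ref <- half_max_time(reference)
  t_can <- half_max_time(candidate)
  if (is.na(t_ref) || is.na(t_can))
    return(list(shift = NA_real_, reference = NULL, candidate = NULL,
                ok = FALSE))
  shift <- t_ref - t_can
  shifted <- candidate$time + shift
  keep <- reference$time >= min(shifted) & reference$time <= max(shifted)
  if (sum(keep) < 2)
    return(list(shift = shift, reference = NULL, candidate = NULL, ok = FALSE))
  v_int <- approx(shifted, candidate$v, xout = reference$time[keep])$y
  list(shift = shift,
       reference = ap_trace(reference$time[keep], reference$v[keep],
                            pcl = reference$pcl,
                            normalized = reference$normalized),
       candidate = ap_trace(reference$time[keep], v_int, pcl = candidate$pcl,
                            normalized = candidate$normalized),
       ok = TRUE)
}

#' Least-squares affine renormalization of the input trace
#'
#' Finds alpha, beta minimizing `sum((alpha * V_ref + beta - V_model)^2)` in
#' closed form (simple linear regression of the model on the reference) and
#' applies them to the reference, mapping the (possibly unit-less optical)
#' input onto the model's absolute-mV scale.
#'
#' @param reference,candidate aligned [ap_trace()]s on a common grid.
#' @return list: `alpha`, `beta`, `rescaled` (the transformed reference).
#' @export
lsq_rescale <- function(reference, candidate) {
  stopifnot(length(reference$v) == length(candidate$v))
  vr <- reference$v
  vm <- candidate$v
  sxx <- sum((vr - mean(vr))^2)
  if (sxx <= 0) stop("zero-variance reference trace")
  alpha <- sum((vr - mean(vr)) * (vm - mean(vm))) / sxx
  beta <- mean(vm) - alpha * mean(vr)
  list(alpha = alpha, beta = beta,
       rescaled = ap_trace(reference$time, alpha * vr + beta,
                           pcl = reference$pcl, normalized = FALSE))
}

#' Root-mean-square error between two traces on a common grid
#' @param reference,candidate equal-length [ap_trace()]s.
#' @return RMSE in mV.
#' @export
ap_rmse <- function(reference, candidate) {
  if (length(reference$v) != length(candidate$v))
    stop("traces must have equal length")
  sqrt(mean((reference$v - candidate$v)^2))
}

#' Reference trace set for the fitness function
#'
#' @param traces list of [ap_trace()], one per distinct PCL.
#' @param weights per-PCL weights (>= 0, not all zero); the weighted sum is
#'   not normalized (only relative fitness matters to the optimizer).
#' @param mode `"optical"` (align + affine rescale + upstroke mask before
#'   each comparison) or `"absolute"` (direct comparison in mV).
#' @return list of class `"baseline_set"`.
#' @export
baseline_set <- function(traces, weights = NULL, mode = c("optical", "absolute")) {
  mode <- match.arg(mode)
  pcls <- vapply(traces, function(x) x$pcl, numeric(1))
  if (anyNA(pcls) || anyDuplicated(pcls))
    stop("baselines need distinct, labelled PCLs")
  if (is.null(weights)) weights <- rep(1, length(traces))
  stopifnot(length(weights) == length(traces), all(weights >= 0),
            any(weights > 0))
  structure(list(traces = traces, pcls = pcls, weights = as.numeric(weights),
                 mode = mode), class = "baseline_set")
}

#' Weighted-RMSE fitness of candidate traces against a baseline set
#'
#' For each PCL the candidate is compared to the baseline: in optical mode
#' the baseline is time-aligned on the half-maximum upstroke, affinely
#' rescaled onto the candidate by least squares, and samples where the
#' candidate is still depolarizing below -20 mV are excluded (photon
#' scattering distorts the experimental upstroke). The total fitness is the
#' weighted sum of per-PCL RMSEs. Candidates with an amplitude below
#' 30 mV at any PCL, failed simulations (`NULL` entries) and alignment
#' failures receive the penalty value.
#'
#' @param baselines a [baseline_set()].
#' @param candidates list of [ap_trace()] (or `NULL` for failed runs), in
#'   the order of `baselines$traces`.
#' @param penalty fitness assigned to discarded candidates (mV).
#' @return list: `total` (weighted sum, mV), `per_pcl` (named RMSEs),
#'   `penalized` (logical).
#' @export
ap_fitness <- function(baselines, candidates, penalty = 1000) {
  stopifnot(inherits(baselines, "baseline_set"),
            length(candidates) == length(baselines$traces))
  n <- length(candidates)
  per <- stats::setNames(rep(NA_real_, n), baselines$pcls)
  for (i in seq_len(n)) {
    cand <- candidates[[i]]
    if (is.null(cand))
      return(list(total = penalty, per_pcl = per, penalized = TRUE))
    if (diff(range(cand$v)) < 30)
      return(list(total = penalty, per_pcl = per, penalized = TRUE))
    ref <- baselines$traces[[i]]
    if (baselines$mode == "optical") {
      # a candidate that never depolarizes beyond the -20 mV mask level has
      # no action potential on the compared support (a strong stimulus alone
      # can deflect V by tens of mV, so the amplitude rule does not catch
      # passive responses); discard it like a sub-threshold AP
      if (max(cand$v) < -20)
        return(list(total = penalty, per_pcl = per, penalized = TRUE))
      al <- align_half_max(cand, ref)   # candidate grid is the model grid
      if (!al$ok)
        return(list(total = penalty, per_pcl = per, penalized = TRUE))
      rs <- lsq_rescale(al$candidate, al$reference)
      # the rescaled input must still be an AP: a collapsing alpha means the
      # candidate is a non-repolarizing plateau that least squares flattens
      # the input onto; such organisms are discarded like sub-threshold APs
      if (diff(range(rs$rescaled$v)) < 30)
        return(list(total = penalty, per_pcl = per, penalized = TRUE))
      mask <- upstroke_mask(al$reference)
      per[i] <- ap_rmse(sub_trace(rs$rescaled, mask),
                        sub_trace(al$reference, mask))
    } else {
      m <- min(length(ref$v), length(cand$v))
      per[i] <- sqrt(mean((ref$v[seq_len(m)] - cand$v[seq_len(m)])^2))
    }
  }
  list(total = sum(baselines$weights * per), per_pcl = per, penalized = FALSE)
}

# samples to keep: everything except the contiguous depolarization prefix
# below -20 mV (defined on the model trace, which knows absolute mV)
upstroke_mask <- function(model_trace) {
  v <- model_trace$v
  up <- which(v >= -20)
  if (!length(up)) return(rep(TRUE, length(v)))
  first_up <- up[1]
  keep <- rep(TRUE, length(v))
  if (first_up > 1) keep[seq_len(first_up - 1)] <- FALSE
  keep
}

sub_trace <- function(tr, keep) {
  # masked comparisons do not need class invariants; plain lists suffice
  structure(list(time = tr$time[keep], v = tr$v[keep], pcl = tr$pcl,
                 normalized = tr$normalized), class = "ap_trace")
}

#' Action-potential biomarkers
#'
#' RMP is the mean of the pre-upstroke diastolic segment (or the trace
#' minimum when the trace starts mid-upstroke), amplitude the peak above
#' RMP, APD the time from the half-maximum activation to `level`%
#' repolarization of the amplitude, and dvdt_max the maximum upstroke slope.
#'
#' @param trace an [ap_trace()].
#' @param level repolarization level in percent (80 or 90 typically).
#' @return list: `apd` (ms, `NA` if the trace never repolarizes to the
#'   level), `amplitude`, `rmp`, `dvdt_max` (units/ms), `t_act` (ms).
#' @export
ap_biomarkers <- function(trace, level = 90) {
  v <- trace$v
  t <- trace$time
  t_act <- half_max_time(trace)
  if (is.na(t_act))
    return(list(apd = NA_real_, amplitude = diff(range(v)), rmp = min(v),
                dvdt_max = NA_real_, t_act = NA_real_))
  pre <- t < t_act - 2
  rmp <- if (sum(pre) >= 3) mean(v[pre]) else min(v)
  peak <- max(v)
  amplitude <- peak - rmp
  target <- peak - level / 100 * amplitude
  after <- t > t_act
  vi <- v[after]
  ti <- t[after]
  below <- which(vi[-1] <= target & vi[-length(vi)] > target)
  apd <- NA_real_
  if (length(below)) {
    i <- below[1]
    frac <- (vi[i] - target) / (vi[i] - vi[i + 1])
    t_rep <- ti[i] + frac * (ti[i + 1] - ti[i])
    apd <- t_rep - t_act
  }
  dvdt <- diff(v) / diff(t)
  list(apd = apd, amplitude = amplitude, rmp = rmp, dvdt_max = max(dvdt),
       t_act = t_act)
}

#' Add white Gaussian noise at a prescribed SNR
#'
#' Noise variance is the mean-removed signal power divided by
#' `10^(snr_db / 10)`.
#'
#' @param trace an [ap_trace()].
#' @param snr_db signal-to-noise ratio (dB); `Inf` returns the trace as is.
#' @param seed optional integer seed for reproducibility.
#' @return noisy [ap_trace()].
#' @export
add_noise <- function(trace, snr_db, seed = NULL) {
  if (!is.finite(snr_db)) return(trace)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  p_sig <- mean((trace$v - mean(trace$v))^2)
  sigma <- sqrt(p_sig / 10^(snr_db / 10))
  ap_trace(trace$time, trace$v + rnorm(length(trace$v), 0, sigma),
           pcl = trace$pcl, normalized = trace$normalized)
}

#' Remove 60 Hz interference with a zero-phase band-stop filter
#'
#' Second-order Butterworth band-stop (default 58-62 Hz) applied
#' forward-backward (zero phase) so that group delay does not distort APD.
#'
#' @param trace an [ap_trace()]; sampling rate must be at least 200 Hz.
#' @param band stop-band edges (Hz).
#' @return filtered [ap_trace()].
#' @export
notch_60hz <- function(trace, band = c(58, 62)) {
  fs <- 1000 / trace_dt(trace)
  if (fs < 200) stop("sampling rate below 200 Hz")
  bf <- signal::butter(2, band / (fs / 2), type = "stop")
  v <- signal::filtfilt(bf, trace$v)
  ap_trace(trace$time, v, pcl = trace$pcl, normalized = trace$normalized)
}

#' Ensemble average of repeated beats
#'
#' Aligns every trace to the first one on the half-maximum upstroke and
#' averages on the common grid; used to improve the SNR of optical
#' recordings.
#'
#' @param traces non-empty list of [ap_trace()]s of one beat each.
#' @return averaged [ap_trace()].
#' @export
ensemble_average <- function(traces) {
  if (!length(traces)) stop("need at least one trace")
  if (length(traces) == 1) return(traces[[1]])
  ref <- traces[[1]]
  acc <- ref$v
  cnt <- rep(1, length(acc))
  for (tr in traces[-1]) {
    al <- align_half_max(ref, tr)
    if (!al$ok) stop("trace without upstroke in ensemble")
    idx <- match(round(al$candidate$time / trace_dt(ref)),
                 round(ref$time / trace_dt(ref)))
    acc[idx] <- acc[idx] + al$candidate$v
    cnt[idx] <- cnt[idx] + 1
  }
  ap_trace(ref$time, acc / cnt, pcl = ref$pcl, normalized = ref$normalized)
}

#' Empirical signal-to-noise ratio of a noisy trace against a clean one
#' @param clean,noisy equal-grid [ap_trace()]s.
#' @return SNR in dB.
#' @export
measure_snr <- function(clean, noisy) {
  p_sig <- mean((clean$v - mean(clean$v))^2)
  p_noise <- mean((noisy$v - clean$v)^2)
  10 * log10(p_sig / p_noise)
}
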