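#' @useDynLib cardiofit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef lm median prcomp rcauchy rnorm runif sd var
#' @importFrom utils read.table write.table
NULL

#' Names of the 13 scaled model parameters
#'
#' Conductances and fluxes of the O'Hara-Rudy endocardial model that are
#' varied multiplicatively by the optimizer: fast/late sodium (gNa), rapid
#' and inward-rectifier and slow delayed-rectifier potassium (gKr, gK1, gKs),
#' L-type calcium permeability (PCaL), transient outward (gto), Na/K pump
#' (gNaK), Na/Ca exchanger (gNCX), sarcolemmal Ca pump (gpCa), SR release and
#' uptake fluxes (Jrel, Jup), calmodulin buffer capacity (CMDN) and the
#' CaMKII pool (CaMKII).
#' @return character vector of length 13.
#' @export
scaling_names <- function() {
  c("gNa", "gKr", "gK1", "gKs", "PCaL", "gto", "gNaK",
    "gNCX", "gpCa", "Jrel", "Jup", "CMDN", "CaMKII")
}

#' Multiplicative scaling factors for the ionic model
#'
#' @param ... named multipliers (unnamed parameters default to 1, the
#'   baseline model). E.g. `scaling_factors(gKr = 0.5)`.
#' @param check if `TRUE`, enforce the search-range bounds \[0.01, 4\].
#' @return named numeric vector of length 13, class `"scaling_factors"`.
#' @export
scaling_factors <- function(..., check = TRUE) {
  s <- stats::setNames(rep(1, 13), scaling_names())
  dots <- c(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!names(dots) %in% scaling_names()))
      stop("unknown scaling factor name(s): ",
           paste(setdiff(names(dots), scaling_names()), collapse = ", "))
    s[names(dots)] <- dots
  }
  if (check && (any(s < 0.01 - 1e-12) || any(s > 4 + 1e-12)))
    stop("scaling factors must lie within [0.01, 4]")
  structure(s, class = "scaling_factors")
}

as_scaling <- function(s) {
  if (inherits(s, "scaling_factors")) return(unclass(s))
  s <- unlist(s)
  if (length(s) != 13) stop("scaling must have 13 components")
  if (!is.null(names(s)) && all(scaling_names() %in% names(s)))
    s <- s[scaling_names()]
  unname(s)
}

#' Published resting steady state of the endocardial model
#'
#' State vector (41 components) of the O'Hara-Rudy endocardial cell after
#' long 1 Hz pacing, as published with the model. Used as the default
#' initial condition; individual components (e.g. the slow concentrations)
#' can be overwritten before a run.
#' @return named numeric vector of length 41.
#' @export
ord_initial_state <- function() {
  ord_initial_state_cpp()
}

check_state <- function(state) {
  nm <- as.character(ord_state_names_cpp())
  if (length(state) != length(nm)) stop("state must have 41 components")
  if (!is.null(names(state))) state <- state[nm]
  if (any(!is.finite(state)))
    stop("non-finite state component: ", nm[which(!is.finite(state))[1]])
  unname(state)
}

#' Right-hand side of the ionic model
#'
#' Time derivative of every state component plus the individual membrane
#' currents (A/F) at a given state, under multiplicative parameter scaling.
#'
#' @param state named state vector (see [ord_initial_state()]).
#' @param scaling [scaling_factors()] vector.
#' @param istim stimulus current (A/F) applied at this instant.
#' @return list with `deriv` (named, per ms) and `currents` (named, A/F;
#'   SR fluxes in mM/ms).
#' @export
ord_rhs <- function(state, scaling = scaling_factors(), istim = 0) {
  ord_rhs_cpp(check_state(state), as_scaling(scaling), istim)
}

#' Nernst equilibrium potential
#'
#' @param valence ionic charge z.
#' @param conc_in,conc_out intra/extracellular concentrations (mM), > 0.
#' @param temperature absolute temperature (K).
#' @return reversal potential in mV.
#' @export
nernst <- function(valence, conc_in, conc_out, temperature = 310) {
  if (any(conc_in <= 0) || any(conc_out <= 0))
    stop("concentrations must be positive")
  1000 * 8.314 * temperature / (valence * 96485) * log(conc_out / conc_in)
}

default_stim <- function() list(amplitude = -80, duration = 0.5)

#' Integrate the single cell over an arbitrary stimulus schedule
#'
#' Adaptive Rush-Larsen integration: gating variables advance by exponential
#' updates, concentrations and voltage by explicit steps, with the step size
#' targeting 0.2 mV of voltage change (floor 5e-3 ms, cap `dt_max`). The
#' voltage trace is resampled onto a uniform 1 ms grid (1 kHz, matching
#' optical recordings).
#'
#' @param state initial state vector.
#' @param scaling [scaling_factors()].
#' @param duration total simulated time (ms).
#' @param stim_times stimulus onset times (ms); empty for an unstimulated run.
#' @param stim_amplitude,stim_duration stimulus current (A/F) and width (ms).
#' @param dt_min,dt_max,dt_out integrator floor/cap and output step (ms).
#' @param record_from discard output before this time (ms).
#' @param pcl cycle-length label attached to the returned trace (ms).
#' @return list with `trace` (an [ap_trace()]), `final_state`, and `ok`
#'   (`FALSE` flags a numerical blow-up; the trace is then unusable but the
#'   caller can assign a penalty instead of crashing).
#' @export
integrate_cell <- function(state, scaling = scaling_factors(), duration,
                           stim_times = numeric(), stim_amplitude = -80,
                           stim_duration = 0.5, dt_min = 5e-3, dt_max = 1,
                           dt_out = 1, record_from = 0, pcl = NA_real_) {
  stopifnot(duration > 0, dt_min > 0, dt_max >= dt_min)
  res <- ord_run_cpp(check_state(state), as_scaling(scaling), duration,
                     as.numeric(stim_times), stim_amplitude, stim_duration,
                     dt_min, dt_max, dt_out, record_from)
  trace <- ap_trace(res$time, res$v, pcl = pcl)
  list(trace = trace, final_state = res$final_state, ok = res$ok)
}

#' Pace the single cell to (or toward) steady state
#'
#' Applies periodic stimuli at a fixed pacing cycle length for `settle_s`
#' seconds and returns the last beat. The beat-to-beat APD90 difference of
#' the final two beats is reported as a convergence measure.
#'
#' @param scaling [scaling_factors()].
#' @param state initial state ([ord_initial_state()] by default).
#' @param pcl pacing cycle length (ms).
#' @param settle_s total pacing time (s); the number of beats is
#'   `floor(settle_s * 1000 / pcl)`, at least 1.
#' @param dt_max integrator step cap (ms).
#' @param stim stimulus as `list(amplitude =, duration =)`.
#' @return list: `trace` (last beat, time restarted at 0), `final_state`,
#'   `apd_diff` (|APD90(last) - APD90(previous)| in ms, NA for single-beat
#'   runs or undefined APDs), `ok`.
#' @export
pace_to_steady_state <- function(scaling = scaling_factors(),
                                 state = ord_initial_state(), pcl,
                                 settle_s = 1000, dt_max = 1,
                                 stim = default_stim()) {
  stopifnot(pcl > 0, settle_s * 1000 >= pcl)
  nbeats <- max(1L, floor(settle_s * 1000 / pcl))
  record_from <- (nbeats - min(nbeats, 2)) * pcl
  res <- integrate_cell(state, scaling, duration = nbeats * pcl,
                        stim_times = (seq_len(nbeats) - 1) * pcl,
                        stim_amplitude = stim$amplitude,
                        stim_duration = stim$duration,
                        dt_max = dt_max, record_from = record_from, pcl = pcl)
  if (!res$ok)
    return(list(trace = NULL, final_state = res$final_state,
                apd_diff = NA_real_, ok = FALSE))
  tr <- res$trace
  last_start <- (nbeats - 1) * pcl
  keep <- tr$time >= last_start
  last <- ap_trace(tr$time[keep] - last_start, tr$v[keep], pcl = pcl)
  apd_diff <- NA_real_
  if (nbeats >= 2) {
    prev_keep <- tr$time >= last_start - pcl & tr$time < last_start
    prev <- ap_trace(tr$time[prev_keep] - (last_start - pcl), tr$v[prev_keep],
                     pcl = pcl)
    a1 <- ap_biomarkers(prev, level = 90)$apd
    a2 <- ap_biomarkers(last, level = 90)$apd
    if (is.finite(a1) && is.finite(a2)) apd_diff <- abs(a2 - a1)
  }
  list(trace = last, final_state = res$final_state, apd_diff = apd_diff,
       ok = TRUE)
}

#' Reference parameters of the closed-form toy action potential
#'
#' @return named vector: resting-level depth `rest` (mV below zero),
#'   amplitude `amp` (mV), long-cycle duration `apd` (ms) and restitution
#'   strength `rst` (dimensionless short-cycle shortening exponent).
#' @export
toy_reference <- function() {
  c(rest = 85, amp = 115, apd = 350, rst = 1)
}

#' Closed-form toy action potential
#'
#' A cheap deterministic surrogate for the ionic model used to exercise the
#' whole fitting machinery in seconds. Each of the four positive shape
#' factors controls exactly one feature: `rest` the resting level (-rest mV),
#' `amp` the amplitude, `apd` the long-cycle duration, and `rst` the
#' strength of rate-dependent shortening,
#' `APD(PCL) = apd * exp(-rst * exp(-(PCL - 300) / 250))`,
#' so short cycles shorten the AP and the effect vanishes at long cycles
#' (standard APD restitution, in a closed form with disentangled controls).
#'
#' @param params named positive vector as in [toy_reference()].
#' @param pcl pacing cycle length (ms); also the trace length.
#' @param dt_out sample interval (ms).
#' @return an [ap_trace()].
#' @export
toy_ap <- function(params = toy_reference(), pcl, dt_out = 1) {
  params <- params[c("rest", "amp", "apd", "rst")]
  if (any(!is.finite(params)) || any(params <= 0))
    stop("toy parameters must be positive")
  t <- seq(0, pcl - dt_out, by = dt_out)
  apd <- params[["apd"]] * exp(-params[["rst"]] * exp(-(pcl - 300) / 250))
  upstroke <- 1 / (1 + exp(-(t - 3) / 0.6))
  repol <- 1 / (1 + exp((t - apd) / (apd / 14)))
  v <- -params[["rest"]] + params[["amp"]] * upstroke * repol
  ap_trace(t, v, pcl = pcl)
}
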