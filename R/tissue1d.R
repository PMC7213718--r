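#' Configuration of the 1D cable
#'
#' A string of ventricular cells coupled by a gap-junctional conductance,
#' used as the forward model when fitting tissue recordings. One node per
#' cell; end cells are no-flux.
#'
#' @param n_cells number of cells (>= 3, default 30).
#' @param coupling gap-junctional coupling (mS/uF, default 5; with the
#'   default geometry this yields a conduction velocity near 27 cm/s).
#' @param cell_length cell length in cm (default 0.01, the published cell
#'   length of the ionic model) used only to convert activation delays into
#'   a conduction velocity.
#' @param stim_cells indices of stimulated cells (default the first
#'   three; pacing a short end segment reliably launches a planar wave).
#' @param record_cell index of the recorded cell (default the center).
#' @return list of class `"cable_config"`.
#' @export
cable_config <- function(n_cells = 30, coupling = 5, cell_length = 0.01,
                         stim_cells = 1:3, record_cell = NULL) {
  stopifnot(n_cells >= 3, coupling > 0, cell_length > 0)
  if (is.null(record_cell)) record_cell <- ceiling(n_cells / 2)
  if (record_cell <= 1 || record_cell >= n_cells)
    stop("recording cell must be interior")
  structure(list(n_cells = as.integer(n_cells), coupling = coupling,
                 cell_length = cell_length,
                 stim_cells = as.integer(stim_cells),
                 record_cell = as.integer(record_cell)),
            class = "cable_config")
}

#' Simulate the paced 1D cable
#'
#' Nearest-neighbour diffusive coupling of the membrane potential with
#' no-flux ends; the diffusion term shares the adaptive step of the cell
#' update, with the cap reduced to keep the explicit scheme stable. Returns
#' the trace at the recording cell, all final cell states, and the per-cell
#' activation times (first -20 mV upstroke crossing) of the last beat.
#'
#' @param config a [cable_config()].
#' @param scaling [scaling_factors()].
#' @param pcl pacing cycle length (ms).
#' @param n_beats number of beats.
#' @param states initial states: a single state vector (broadcast) or a
#'   matrix with one row per cell.
#' @param stim stimulus `list(amplitude =, duration =)`; the tissue
#'   default is -80 A/F for 2 ms (a longer pulse than the single-cell one,
#'   since gap-junctional loading raises the end-stimulation threshold).
#' @param dt_max step cap (ms) before the stability reduction.
#' @return list: `trace` (last beat at the recording cell), `final_states`
#'   (matrix), `activation` (ms within the last beat; `NA` where a cell
#'   never activated), `ok` (`FALSE` on numerical failure or when no cell
#'   beyond the stimulus site activates).
#' @export
simulate_cable <- function(config, scaling = scaling_factors(), pcl,
                           n_beats = 5, states = ord_initial_state(),
                           stim = list(amplitude = -80, duration = 2),
                           dt_max = 1) {
  stopifnot(inherits(config, "cable_config"), pcl > 0, n_beats >= 1)
  if (is.null(dim(states)))
    states <- matrix(check_state(states), nrow = config$n_cells,
                     ncol = 41, byrow = TRUE)
  stopifnot(nrow(states) == config$n_cells, ncol(states) == 41)
  last_start <- (n_beats - 1) * pcl
  res <- cable_run_cpp(states, as_scaling(scaling), n_beats * pcl,
                       (seq_len(n_beats) - 1) * pcl,
                       stim$amplitude, stim$duration,
                       config$stim_cells - 1L, config$coupling,
                       5e-3, dt_max, 1, last_start, config$record_cell - 1L,
                       last_start)
  act <- res$activation - last_start
  propagated <- any(is.finite(act[-config$stim_cells]))
  ok <- isTRUE(res$ok) && propagated
  trace <- if (isTRUE(res$ok))
    ap_trace(res$time - last_start, res$v, pcl = pcl) else NULL
  list(trace = trace, final_states = res$final_states, activation = act,
       ok = ok)
}

#' Conduction velocity from per-cell activation times
#'
#' Least-squares slope of distance versus activation time over the interior
#' cells (5 cells at each boundary excluded to avoid stimulus and no-flux
#' edge artifacts).
#'
#' @param activation activation times (ms), one per cell, increasing away
#'   from the stimulated end.
#' @param cell_length cell spacing (cm).
#' @param trim cells excluded at each boundary.
#' @return conduction velocity in cm/s.
#' @export
conduction_velocity <- function(activation, cell_length = 0.01, trim = 5) {
  n <- length(activation)
  idx <- seq.int(trim + 1, n - trim)
  if (length(idx) < 2) stop("need at least 2 interior activation times")
  act <- activation[idx]
  if (anyNA(act)) stop("conduction block: unactivated interior cells")
  if (any(diff(act) < 0)) stop("non-monotone activation (block or re-entry)")
  if (max(act) - min(act) <= 0) stop("identical activation times (infinite CV)")
  x <- (idx - 1) * cell_length
  slope <- coef(lm(x ~ act))[[2]]   # cm/ms
  slope * 1000
}
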