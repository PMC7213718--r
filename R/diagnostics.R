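#' Project population snapshots onto the first two principal components
#'
#' Snapshots (organisms x the 13 scaling multipliers; slow-variable genes
#' excluded) from one or more generations are pooled, mean-centered (the
#' multipliers are already baseline-normalized and dimensionless, so no
#' variance scaling is applied) and decomposed. The optional true parameter
#' vector is projected into the same plane.
#'
#' @param snapshots a matrix, or a list of matrices with identical columns.
#' @param reference optional true multiplier vector.
#' @return list: `scores` (n x 2, with a `generation` attribute mapping rows
#'   to snapshots), `loadings` (p x 2), `explained` (fraction of variance per
#'   component), `reference_score` (length-2 or `NULL`), `center`.
#' @export
pca_project <- function(snapshots, reference = NULL) {
  if (is.matrix(snapshots)) snapshots <- list(snapshots)
  x <- do.call(rbind, snapshots)
  if (nrow(x) < 3) stop("need at least 3 organisms")
  gen <- rep(seq_along(snapshots), vapply(snapshots, nrow, integer(1)))
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  if (qr(xc)$rank < 1) stop("degenerate population (zero variance)")
  pc <- prcomp(xc, center = FALSE, scale. = FALSE)
  k <- min(2, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  if (k == 1) scores <- cbind(scores, 0)
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  ref_score <- NULL
  if (!is.null(reference)) {
    ref_score <- as.numeric((reference - ctr) %*% loadings)
    if (length(ref_score) == 1) ref_score <- c(ref_score, 0)
  }
  attr(scores, "generation") <- gen
  list(scores = scores, loadings = loadings,
       explained = expl[seq_len(min(2, length(expl)))],
       reference_score = ref_score, center = ctr)
}

#' Mean Cluster Error
#'
#' Euclidean distance in the principal-component plane between the cluster
#' centroid of one generation and the projection of the true parameters.
#'
#' @param scores n x 2 score matrix of the organisms of one generation.
#' @param reference_score length-2 projection of the true parameter vector.
#' @return distance (same units as the scores).
#' @export
mce <- function(scores, reference_score) {
  scores <- rbind(scores)
  ctr <- colMeans(scores[, 1:2, drop = FALSE])
  sqrt(sum((ctr - reference_score[1:2])^2))
}

#' Standard Distance of a score cluster
#'
#' Square root of the summed mean squared deviations about the centroid in
#' the two principal-component coordinates; the cluster-size measure.
#'
#' @param scores n x 2 score matrix.
#' @return spread (same units as the scores).
#' @export
sdist <- function(scores) {
  scores <- rbind(scores)
  x <- scores[, 1]; y <- scores[, 2]
  sqrt(mean((x - mean(x))^2) + mean((y - mean(y))^2))
}

#' Per-parameter recovery errors across runs
#'
#' Relative errors `|estimate - truth| / truth` of the scaling multipliers
#' of the best organisms of several runs, reported in percent as mean and
#' SD per parameter.
#'
#' @param best_genomes list (or matrix rows) of fitted genomes; only the
#'   entries named in `truth` are used.
#' @param truth named true multiplier vector (all non-zero).
#' @return data.frame: `parameter`, `mean_pct`, `sd_pct`, plus a matrix
#'   attribute `"errors"` (runs x parameters, percent).
#' @export
recovery_report <- function(best_genomes, truth) {
  if (any(truth == 0)) stop("truth contains zero; relative error undefined")
  if (is.matrix(best_genomes))
    best_genomes <- split(best_genomes, row(best_genomes))
  err <- t(vapply(best_genomes, function(g) {
    g <- unlist(g)
    abs(g[names(truth)] - truth) / abs(truth) * 100
  }, numeric(length(truth))))
  colnames(err) <- names(truth)
  out <- data.frame(parameter = names(truth),
                    mean_pct = colMeans(err),
                    sd_pct = if (nrow(err) > 1) apply(err, 2, sd) else 0,
                    row.names = NULL)
  attr(out, "errors") <- err
  out
}
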