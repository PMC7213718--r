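#' Write / read an AP trace as two-column delimited text
#'
#' Columns `time_ms` and `v`; the PCL label and normalization flag travel
#' in a `# pcl:`/`# normalized:` comment header.
#' @param trace an [ap_trace()].
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pcl: %s", format(trace$pcl)),
               sprintf("# normalized: %s", trace$normalized),
               "time_ms\tv"), con)
  write.table(data.frame(trace$time, trace$v), con, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @return `read_trace` returns an [ap_trace()].
#' @export
read_trace <- function(path) {
  hdr <- readLines(path, n = 2)
  pcl <- as.numeric(sub("# pcl: *", "", hdr[1]))
  normalized <- identical(sub("# normalized: *", "", hdr[2]), "TRUE")
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  ap_trace(df[[1]], df[[2]], pcl = pcl, normalized = normalized)
}

#' Write / read a baseline set as a directory of traces plus a manifest
#'
#' One `pcl_<PCL>.tsv` per trace and a `manifest.yaml` carrying PCLs,
#' weights and the comparison mode.
#' @param baselines a [baseline_set()].
#' @param dir directory (created if needed).
#' @export
write_baseline_set <- function(baselines, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("pcl_%g.tsv", baselines$pcls)
  for (i in seq_along(files))
    write_trace(baselines$traces[[i]], file.path(dir, files[i]))
  yaml::write_yaml(list(pcls = as.list(baselines$pcls),
                        weights = as.list(baselines$weights),
                        mode = baselines$mode, files = as.list(files)),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_baseline_set
#' @return `read_baseline_set` returns a [baseline_set()].
#' @export
read_baseline_set <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  traces <- lapply(man$files, function(f) read_trace(file.path(dir, f)))
  baseline_set(traces, weights = unlist(man$weights), mode = man$mode)
}

#' Write / read a genome (or scaling factors) as JSON
#' @param genome named numeric vector.
#' @param path file path.
#' @export
write_genome <- function(genome, path) {
  jsonlite::write_json(as.list(unclass(genome)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write / read a cell state as flat named-vector JSON
#' @param state named state vector.
#' @param path file path.
#' @export
write_state <- function(state, path) {
  jsonlite::write_json(as.list(state), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  unlist(jsonlite::read_json(path, simplifyVector = TRUE))
}

read_ga_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cab <- if (!is.null(y$cable)) do.call(cable_config, y$cable) else NULL
  y$cable <- NULL
  do.call(ga_config, c(y, if (!is.null(cab)) list(cable = cab)))
}

#' Workflow commands behind the command-line interface
#'
#' Thin file-in/file-out wrappers tying the modules into the two workflows:
#' fitting a subject from AP baselines and rescale-and-predict via mRNA
#' ratios. The `inst/cli/cardiofit` script dispatches to these.
#'
#' @param scaling_json optional JSON of scaling factors (baseline if `NULL`).
#' @param pcl,pcls pacing cycle length(s), ms.
#' @param n_beats beats to simulate.
#' @param out,out_dir output paths.
#' @param seed integer seed.
#' @name cli
#' @return the main output path, invisibly.
NULL

#' @rdname cli
#' @export
cmd_simulate <- function(scaling_json = NULL, pcl = 1000, n_beats = 9,
                         out = "trace.tsv") {
  s <- if (is.null(scaling_json)) scaling_factors()
       else read_genome(scaling_json)[scaling_names()]
  res <- pace_cell_beats(ord_initial_state(), s, pcl, n_beats,
                         default_stim(), 1)
  if (!res$ok) stop("simulation failed (non-finite state)")
  write_trace(res$trace, out)
  invisible(out)
}

#' @rdname cli
#' @param settle_s,snr_db,mode forwarded to [make_baselines()].
#' @export
cmd_make_baselines <- function(scaling_json = NULL, pcls = c(300, 500, 1000, 2000),
                               settle_s = 100, snr_db = Inf, seed = 1,
                               mode = "optical", out_dir = "baselines") {
  s <- if (is.null(scaling_json)) scaling_factors()
       else read_genome(scaling_json)[scaling_names()]
  bs <- make_baselines(s, pcls, settle_s = settle_s, snr_db = snr_db,
                       seed = seed, mode = mode)
  write_baseline_set(bs, out_dir)
  truth <- attr(bs, "truth")
  write_genome(truth$scaling, file.path(out_dir, "truth_scaling.json"))
  invisible(out_dir)
}

#' @rdname cli
#' @param baselines_dir directory written by [cmd_make_baselines()].
#' @param config_yaml YAML of [ga_config()] fields (defaults if `NULL`).
#' @export
cmd_fit <- function(baselines_dir, config_yaml = NULL, seed = 1,
                    out_dir = "run") {
  bs <- read_baseline_set(baselines_dir)
  cfg <- if (is.null(config_yaml)) ga_config() else read_ga_yaml(config_yaml)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  res <- run_ga(cfg, bs)
  write.table(res$history, file.path(out_dir, "history.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  write_genome(res$best$genome, file.path(out_dir, "best_genome.json"))
  jsonlite::write_json(list(seed = seed, mode = cfg$mode,
                            population = cfg$population,
                            generations = cfg$generations,
                            best_fitness = res$best$fitness),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @rdname cli
#' @param genome_json fitted genome JSON.
#' @param expr_tsv expression table ([read_expression_table()]).
#' @param reference,target sample names.
#' @export
cmd_rescale <- function(genome_json, expr_tsv, reference, target,
                        out = "rescaled.json") {
  g <- read_genome(genome_json)
  expr <- read_expression_table(expr_tsv)
  s <- rescale_by_expression(g, expr, reference, target)
  write_genome(s, out)
  invisible(out)
}

#' @rdname cli
#' @param run_dir directory written by [cmd_fit()].
#' @param truth_json JSON of the true multipliers.
#' @export
cmd_report <- function(run_dir, truth_json, out = file.path(run_dir, "report.tsv")) {
  g <- read_genome(file.path(run_dir, "best_genome.json"))
  truth <- read_genome(truth_json)
  truth <- truth[intersect(names(truth), names(g))]
  rep <- recovery_report(list(g), truth)
  write.table(rep, out, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
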