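# Report writers: the three published analyses as files on disk, each run
# accompanied by a JSON manifest sufficient to reproduce it.

as_bundle <- function(config) {
  if (inherits(config, "cua_bundle")) return(config)
  load_config(config)
}

write_manifest <- function(output_dir, command, config, seed = NA,
                           n_draws = NA) {
  manifest <- list(
    command = command,
    config_path = if (is.character(config)) config else "<in-memory bundle>",
    seed = seed,
    n_draws = n_draws,
    output_dir = output_dir,
    software_version = as.character(utils::packageVersion("afcua")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Write the base-case analysis to a directory
#'
#' Produces `results.csv` (the published table layout: cost, QALYs,
#' incremental cost, incremental QALYs, ICER), `results.json`, per-strategy
#' cohort traces (`trace_rfa.csv`, `trace_cba.csv`), the parameter set used
#' (`parameters.yaml`), and `manifest.json`.
#'
#' @param config a `cua_bundle` or the path of a YAML configuration file.
#' @param output_dir directory to write into (created if needed).
#' @return the output directory, invisibly.
#' @export
report_base <- function(config, output_dir) {
  bundle <- as_bundle(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- cua(bundle)
  write_results(fit, file.path(output_dir, "results.csv"))
  write_results(fit, file.path(output_dir, "results.json"))
  write_trace(fit$rfa$trace, file.path(output_dir, "trace_rfa.csv"))
  write_trace(fit$cba$trace, file.path(output_dir, "trace_cba.csv"))
  write_config(bundle, file.path(output_dir, "parameters.yaml"))
  write_manifest(output_dir, "base", config)
  invisible(output_dir)
}

#' Write the deterministic sensitivity analyses to a directory
#'
#' Produces `tornado.csv` (sorted by ICER spread), `one_way_<param>.csv`
#' curves for each requested parameter, `two_way.csv` (verdict grid over the
#' two procedure costs), `thresholds.csv` (threshold value per parameter, or
#' a recorded no-threshold outcome), and `manifest.json`.
#'
#' @param config a `cua_bundle` or YAML configuration path.
#' @param output_dir directory to write into.
#' @param parameters dotted parameter paths (default [tornado_parameters()]).
#' @param grid_points grid resolution for the one-way and two-way sweeps.
#' @return the output directory, invisibly.
#' @export
report_dsa <- function(config, output_dir,
                       parameters = tornado_parameters(),
                       grid_points = 11) {
  bundle <- as_bundle(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  torn <- tornado(bundle, parameters)
  utils::write.csv(as.data.frame(torn), file.path(output_dir, "tornado.csv"),
                   row.names = FALSE)
  for (p in parameters) {
    bnd <- param_bounds(bundle, p)
    grid <- seq(bnd[["low"]], bnd[["high"]], length.out = grid_points)
    ow <- one_way(bundle, p, grid)
    utils::write.csv(ow, file.path(output_dir,
                                   paste0("one_way_", gsub("\\.", "_", p),
                                          ".csv")),
                     row.names = FALSE)
  }
  tw <- two_way(bundle, "rfa.cost_procedure", "cba.cost_procedure",
                grid_a = seq(param_bounds(bundle, "rfa.cost_procedure")[1],
                             param_bounds(bundle, "rfa.cost_procedure")[2],
                             length.out = grid_points),
                grid_b = seq(param_bounds(bundle, "cba.cost_procedure")[1],
                             param_bounds(bundle, "cba.cost_procedure")[2],
                             length.out = grid_points))
  utils::write.csv(data.frame(rfa_cost = rep(rownames(tw), ncol(tw)),
                              cba_cost = rep(colnames(tw), each = nrow(tw)),
                              verdict = as.vector(tw)),
                   file.path(output_dir, "two_way.csv"), row.names = FALSE)
  thr <- do.call(rbind, lapply(parameters, function(p) {
    res <- tryCatch(find_threshold(bundle, p),
                    afcua_threshold_error = function(e) NULL)
    if (is.null(res))
      data.frame(parameter = p, value_at_threshold = NA_real_,
                 found = FALSE)
    else
      data.frame(parameter = p, value_at_threshold = res$value_at_threshold,
                 found = TRUE)
  }))
  utils::write.csv(thr, file.path(output_dir, "thresholds.csv"),
                   row.names = FALSE)
  write_manifest(output_dir, "dsa", config)
  invisible(output_dir)
}

#' Write the probabilistic sensitivity analysis to a directory
#'
#' Produces `psa_scatter.csv` (one row per draw: incremental cost, QALYs,
#' plane component), `quadrants.csv` (the six-component report with
#' frequencies and proportions plus the two cost-effectiveness
#' probabilities), `ceac.csv`, and `manifest.json` recording the seed.
#'
#' @param config a `cua_bundle` or YAML configuration path.
#' @param output_dir directory to write into.
#' @param n_draws Monte Carlo repetitions.
#' @param seed integer RNG seed.
#' @param wtp_grid thresholds for the acceptability curve.
#' @return the output directory, invisibly.
#' @export
report_psa <- function(config, output_dir, n_draws = 10000, seed = 1,
                       wtp_grid = seq(0, 30000, by = 1000)) {
  bundle <- as_bundle(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  psa <- run_psa(bundle, n_draws = n_draws, seed = seed)
  utils::write.csv(psa$samples, file.path(output_dir, "psa_scatter.csv"),
                   row.names = FALSE)
  q <- as.data.frame(psa$quadrants)
  q$p_cost_effective_new <- attr(psa$quadrants, "p_cost_effective_new")
  q$p_cost_effective_comparator <-
    attr(psa$quadrants, "p_cost_effective_comparator")
  utils::write.csv(q, file.path(output_dir, "quadrants.csv"),
                   row.names = FALSE)
  utils::write.csv(ceac(psa, wtp_grid), file.path(output_dir, "ceac.csv"),
                   row.names = FALSE)
  write_manifest(output_dir, "psa", config, seed = seed, n_draws = n_draws)
  invisible(output_dir)
}
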