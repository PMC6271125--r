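# Reporting layer: summary tables, curve decomposition, run manifests,
# and the command-style entry points wrapped by the inst/cli script.

#' Decompose the net curve into its adsorption and release components
#'
#' @param params a [kinetic_params()].
#' @param grid times in minutes.
#' @return data.frame with columns `t`, `C_ads`, `C_rel`, `C_net`
#'   (`C_net = C_ads - C_rel` at every time).
#' @export
decompose_curves <- function(params, grid) {
  grid <- check_times(as.numeric(grid))
  ads <- adsorption_conc(params, grid)
  rel <- release_conc(params, grid)
  data.frame(t = grid, C_ads = ads, C_rel = rel, C_net = ads - rel)
}

#' Summary row for one fitted triplicate
#'
#' @param fit a `compound_fit`.
#' @return One-row data.frame in the summary-table shape: `compound`,
#'   `condition`, `W`, `F_percent`, per-parameter mean and RSD, and
#'   `total_rmse`.
#' @export
fit_summary_row <- function(fit) {
  data.frame(
    compound = fit$compound, condition = fit$condition,
    W = fit$W, F_percent = fit$F,
    mean_k1 = fit$param_means[["k1"]], rsd_k1 = fit$rsd[["k1"]],
    mean_k2 = fit$param_means[["k2"]], rsd_k2 = fit$rsd[["k2"]],
    mean_tau1 = fit$param_means[["tau1"]], rsd_tau1 = fit$rsd[["tau1"]],
    mean_tau2 = fit$param_means[["tau2"]], rsd_tau2 = fit$rsd[["tau2"]],
    total_rmse = fit$total_rmse,
    converged = fit$all_converged,
    stringsAsFactors = FALSE
  )
}

write_manifest <- function(path, command, config, seed, inputs = character(),
                           outputs = character()) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  manifest <- list(
    command = command,
    package = "spmekin",
    version = as.character(utils::packageVersion("spmekin")),
    seed = seed,
    config = config[c(
      "k_init_range", "bounds", "min_tau_separation", "multistart_count", "ridge_tolerance",
      "tolerance", "max_iterations", "seed"
    )],
    input_md5 = digests,
    outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Fit every triplicate in a CSV and write summary outputs
#'
#' Reads replicate profiles, normalizes each run by its final-time
#' area, optionally withholds a validation point per replicate, runs
#' the two-loop fit ([optimize_W()]) per compound/condition, and writes
#' `fits.csv` (one summary row per group), `w_trace.csv` (the outer
#' (W, F) scans), `validation.csv` when a hold-out time is given, and a
#' `manifest.json` capturing config, seed and input digests.
#'
#' @param input path to a profiles CSV (see [read_profiles()]).
#' @param output_dir directory for outputs (created if needed).
#' @param config a [fit_config()].
#' @param W_bounds outer search interval, default `c(1, 1000)`.
#' @param holdout_time optional validation time in minutes; when given,
#'   the point is excluded from fitting and predicted afterwards.
#' @return Invisibly, a list with `fits` (list of `compound_fit`),
#'   `summary` (data.frame), and `validation` (data.frame or `NULL`).
#' @export
cmd_fit <- function(input, output_dir, config = fit_config(),
                    W_bounds = c(1, 1000), holdout_time = NULL) {
  sets <- read_profiles(input)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- list()
  val_rows <- list()
  traces <- list()
  for (key in names(sets)) {
    set <- normalize_set(sets[[key]])
    if (!is.null(holdout_time)) {
      set <- select_validation_point(set, holdout_time)
    }
    fit <- optimize_W(set, config, W_bounds)
    fits[[key]] <- fit
    traces[[key]] <- cbind(
      compound = fit$compound, condition = fit$condition, fit$trace
    )
    if (!is.null(holdout_time)) {
      val_rows[[key]] <- validate_holdout(fit, set)
    }
  }
  summary_df <- do.call(rbind, lapply(fits, fit_summary_row))
  rownames(summary_df) <- NULL
  fits_path <- file.path(output_dir, "fits.csv")
  utils::write.csv(summary_df, fits_path, row.names = FALSE)
  trace_path <- file.path(output_dir, "w_trace.csv")
  utils::write.csv(do.call(rbind, traces), trace_path, row.names = FALSE)
  outputs <- c(fits_path, trace_path)
  validation <- NULL
  if (length(val_rows) > 0) {
    validation <- do.call(rbind, val_rows)
    rownames(validation) <- NULL
    val_path <- file.path(output_dir, "validation.csv")
    utils::write.csv(validation, val_path, row.names = FALSE)
    outputs <- c(outputs, val_path)
  }
  write_manifest(
    file.path(output_dir, "manifest.json"),
    command = "fit", config = config, seed = config$seed,
    inputs = input, outputs = outputs
  )
  invisible(list(fits = fits, summary = summary_df, validation = validation))
}

resolve_scenario <- function(scenario, seed = NULL) {
  if (inherits(scenario, "sim_scenario")) {
    if (!is.null(seed)) scenario$seed <- as.integer(seed)
    return(scenario)
  }
  presets <- preset_scenarios(seed = if (is.null(seed)) 1L else seed)
  if (!scenario %in% names(presets)) {
    stop(
      "unknown scenario '", scenario, "'; available presets: ",
      paste(names(presets), collapse = ", ")
    )
  }
  presets[[scenario]]
}

#' Simulate a triplicate and write it as a profiles CSV
#'
#' @param scenario a [sim_scenario()] or the name of a preset from
#'   [preset_scenarios()].
#' @param output path of the CSV to write.
#' @param seed optional override of the scenario seed.
#' @return Invisibly, the generated [replicate_set()].
#' @export
cmd_simulate <- function(scenario, output, seed = NULL) {
  scenario <- resolve_scenario(scenario, seed)
  set <- generate_replicates(scenario)
  write_profiles(set, output)
  invisible(set)
}

#' Fit with a hold-out point and write the validation report
#'
#' Convenience wrapper around [cmd_fit()] with a mandatory hold-out
#' time: fits every triplicate in `input` without the point at
#' `holdout_time` and writes `validation.csv` comparing predictions to
#' the withheld observations.
#'
#' @inheritParams cmd_fit
#' @param holdout_time validation time in minutes (e.g. 300 for
#'   beverage grids, 20 for gum grids).
#' @return Invisibly, the validation data.frame.
#' @export
cmd_validate <- function(input, output_dir, holdout_time,
                         config = fit_config(), W_bounds = c(1, 1000)) {
  if (is.null(holdout_time)) stop("cmd_validate requires a holdout_time")
  res <- cmd_fit(input, output_dir,
    config = config, W_bounds = W_bounds,
    holdout_time = holdout_time
  )
  invisible(res$validation)
}
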