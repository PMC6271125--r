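# Hold-out validation: predict the withheld late-time point of each
# replicate from parameters fitted without it.

#' Predict the withheld validation points of a triplicate
#'
#' For each replicate, evaluates the fitted net kinetic curve at the
#' hold-out time (a point excluded from every fitting residual) and
#' reports the percent discrepancy
#' `100 * (predicted - observed) / observed`; positive values are
#' over-predictions. Runs whose sampling window ended before
#' equilibrium tend to show positive discrepancies, because the final
#' (normalizing) point then underestimates the true plateau.
#'
#' @param fit a `compound_fit` from [evaluate_F()] or [optimize_W()],
#'   produced from the same hold-out view of `set`.
#' @param set the [replicate_set()] with holdouts populated by
#'   [select_validation_point()].
#' @return An object of class `validation_report`: a data.frame with
#'   columns `compound`, `condition`, `replicate`, `t_holdout`,
#'   `observed`, `predicted`, `discrepancy_percent`, with the summary
#'   `max_abs_discrepancy` attached as an attribute.
#' @export
validate_holdout <- function(fit, set) {
  rows <- Map(function(p, rf) {
    if (is.null(p$holdout)) {
      stop(sprintf(
        "replicate %s of %s / %s has no holdout point; run select_validation_point() first",
        p$replicate, p$compound, p$condition
      ))
    }
    pred <- net_conc(rf$params, p$holdout$time)
    obs <- p$holdout$area
    data.frame(
      compound = p$compound, condition = p$condition,
      replicate = p$replicate, t_holdout = p$holdout$time,
      observed = obs, predicted = pred,
      discrepancy_percent = 100 * (pred - obs) / obs,
      stringsAsFactors = FALSE
    )
  }, set$profiles, fit$replicate_fits)
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "max_abs_discrepancy") <- max(abs(report$discrepancy_percent))
  class(report) <- c("validation_report", "data.frame")
  report
}

#' @export
print.validation_report <- function(x, ...) {
  print.data.frame(x, ...)
  cat(sprintf(
    "max |discrepancy| = %.2f%%\n", attr(x, "max_abs_discrepancy")
  ))
  invisible(x)
}
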