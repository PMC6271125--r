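# Outer loop: optimize the shared peak weight W per compound/condition
# to minimize F, the summed RSD of the four kinetic parameters across
# the triplicate fits.

#' Fit a triplicate at a fixed weighting factor
#'
#' Runs [fit_replicate()] on each of the three replicates with the same
#' `W` and the same seed policy (each fit re-seeds from `config$seed`,
#' so `F(W)` is a deterministic function during the outer search), then
#' summarizes reproducibility: the RSD of each of `k1, k2, tau1, tau2`
#' across the replicate estimates and their sum `F`.
#'
#' @param W shared peak weighting factor, `>= 1`.
#' @param set a normalized [replicate_set()] (holdouts, if used,
#'   already selected).
#' @param config a [fit_config()].
#' @return An object of class `compound_fit`: `replicate_fits`, `W`,
#'   `F` (percent, `= rsd_k1 + rsd_k2 + rsd_tau1 + rsd_tau2` exactly),
#'   `rsd` (named vector of the four RSDs), `param_means`, `total_rmse`
#'   (sum of the three per-replicate RMSEs), and `all_converged`.
#' @export
evaluate_F <- function(W, set, config = fit_config()) {
  fits <- lapply(set$profiles, fit_replicate, W = W, config = config)
  pmat <- vapply(
    fits,
    function(f) unlist(f$params[c("k1", "k2", "tau1", "tau2")]),
    numeric(4)
  )
  rsds <- apply(pmat, 1, rsd)
  names(rsds) <- c("k1", "k2", "tau1", "tau2")
  f_value <- sum(rsds)
  structure(
    list(
      compound = set$compound, condition = set$condition,
      replicate_fits = fits, W = W, F = f_value, rsd = rsds,
      param_means = rowMeans(pmat),
      total_rmse = sum(vapply(fits, `[[`, 0, "rmse")),
      all_converged = all(vapply(fits, `[[`, TRUE, "converged")),
      trace = NULL
    ),
    class = "compound_fit"
  )
}

#' @export
print.compound_fit <- function(x, ...) {
  cat(sprintf(
    "compound_fit: %s / %s\n  W = %.2f, F = %.2f%%, total RMSE = %.3f%s\n",
    x$compound, x$condition, x$W, x$F, x$total_rmse,
    if (x$all_converged) "" else " [non-convergent replicate(s)]"
  ))
  cat(sprintf(
    "  means: k1 = %.4g, k2 = %.4g, tau1 = %.4g, tau2 = %.4g\n",
    x$param_means[1], x$param_means[2], x$param_means[3], x$param_means[4]
  ))
  cat(sprintf(
    "  RSD%%:  k1 = %.2f, k2 = %.2f, tau1 = %.2f, tau2 = %.2f\n",
    x$rsd["k1"], x$rsd["k2"], x$rsd["tau1"], x$rsd["tau2"]
  ))
  invisible(x)
}

#' Optimize the weighting factor for one triplicate
#'
#' Scans `F(W)` over a log-spaced grid inside `W_bounds`, then refines
#' around the best grid point with derivative-free scalar minimization
#' (golden-section/parabolic search on `log10 W`), and returns the
#' [evaluate_F()] result at the best `W` found. Because the inner fits
#' re-seed identically at every `W`, the scan is deterministic and the
#' returned fit is reproducible.
#'
#' A small optimized `W` is expected when the triplicates agree on the
#' peak location and height; large `W` when peak time/height (or the
#' points around the peak) differ notably across replicates.
#'
#' @param set a normalized [replicate_set()].
#' @param config a [fit_config()].
#' @param W_bounds search interval, default `c(1, 1000)`; the lower
#'   bound must be `>= 1`.
#' @param n_grid number of coarse grid points (default 13).
#' @return A `compound_fit` whose `trace` field holds the scanned
#'   `(W, F)` pairs as a data.frame.
#' @export
optimize_W <- function(set, config = fit_config(), W_bounds = c(1, 1000),
                       n_grid = 13) {
  if (length(W_bounds) != 2 || W_bounds[1] >= W_bounds[2]) {
    stop("W_bounds must be c(lower, upper) with lower < upper")
  }
  if (W_bounds[1] < 1) {
    stop("the lower W bound must be >= 1 (W never deprioritizes the peak)")
  }
  trace_w <- numeric(0)
  trace_f <- numeric(0)
  f_of <- function(W) {
    f <- evaluate_F(W, set, config)$F
    trace_w <<- c(trace_w, W)
    trace_f <<- c(trace_f, f)
    f
  }
  grid <- 10^seq(log10(W_bounds[1]), log10(W_bounds[2]), length.out = n_grid)
  f_grid <- vapply(grid, f_of, 0)
  i <- which.min(f_grid)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_grid, i + 1)]
  if (hi > lo) {
    stats::optimize(function(lw) f_of(10^lw), c(log10(lo), log10(hi)),
      tol = 0.02
    )
  }
  best_w <- trace_w[which.min(trace_f)]
  fit <- evaluate_F(best_w, set, config)
  fit$trace <- data.frame(W = trace_w, F = trace_f)
  fit
}
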