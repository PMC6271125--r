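# Synthetic triplicate extraction-time profiles with the statistical
# structure the fitting pipeline assumes: per-replicate parameter
# jitter plus multiplicative measurement noise on a sparse time grid.

#' Default sampling grids
#'
#' Sparse extraction-time grids (minutes): liquid (alcoholic-beverage)
#' profiles run to 300 min, the semi-solid (chewing-gum) grid to 20
#' min, matching the usual hold-out validation times of the two
#' matrices.
#'
#' @return Numeric vector of minutes.
#' @export
beverage_grid <- function() c(5, 10, 20, 30, 45, 60, 90, 120, 180, 240, 300)

#' @rdname beverage_grid
#' @export
gum_grid <- function() c(1, 2, 3, 5, 8, 12, 16, 20)

#' Define a simulation scenario
#'
#' @param true_params a [kinetic_params()] on the normalized scale
#'   (plateau `k1 - k2 = 1` by convention).
#' @param time_grid sampling times in minutes; defaults to
#'   [beverage_grid()].
#' @param obs_noise_cv coefficient of variation of the multiplicative
#'   lognormal measurement noise (default 0.03). GC peak areas are
#'   positive and heteroscedastic, which the lognormal reproduces.
#' @param param_jitter_cv per-replicate relative jitter applied to each
#'   parameter (default 0.01): one mean-one lognormal factor with this
#'   coefficient of variation scales the amplitude pair and an
#'   independent factor the time-constant pair, so the parameter
#'   invariants and the overshoot shape are preserved while peak times
#'   and levels vary between replicates.
#' @param raw_scale optional multiplier to emit raw-like peak areas
#'   (e.g. `1e8`); `NULL` leaves the normalized scale.
#' @param seed integer seed; replicate `i` draws from stream
#'   `seed + i - 1`.
#' @param compound,condition labels for the emitted profiles.
#' @param truncated set `TRUE` for scenarios that deliberately stop
#'   sampling before equilibrium; otherwise the grid must extend to at
#'   least `3 * tau2`.
#' @return An object of class `sim_scenario`.
#' @export
sim_scenario <- function(true_params,
                         time_grid = beverage_grid(),
                         obs_noise_cv = 0.03,
                         param_jitter_cv = 0.01,
                         raw_scale = NULL,
                         seed = 1L,
                         compound = "synthetic",
                         condition = "simulation",
                         truncated = FALSE) {
  stopifnot(inherits(true_params, "kinetic_params"))
  time_grid <- sort(as.numeric(time_grid))
  if (length(time_grid) < 5 || any(time_grid <= 0)) {
    stop("time_grid needs at least 5 positive times")
  }
  if (obs_noise_cv < 0 || param_jitter_cv < 0) {
    stop("noise and jitter coefficients of variation must be >= 0")
  }
  if (!truncated && max(time_grid) < 3 * true_params$tau2) {
    stop(
      "the grid ends before 3 * tau2; pass truncated = TRUE for a ",
      "deliberate non-equilibrium scenario"
    )
  }
  structure(
    list(
      true_params = true_params, time_grid = time_grid,
      obs_noise_cv = obs_noise_cv, param_jitter_cv = param_jitter_cv,
      raw_scale = raw_scale, seed = as.integer(seed),
      compound = compound, condition = condition, truncated = truncated
    ),
    class = "sim_scenario"
  )
}

# Mean-one multiplicative lognormal factors at coefficient of variation cv.
lognormal_factors <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

# Replicate-to-replicate jitter: one mean-one lognormal factor at
# coefficient of variation cv multiplies the amplitude pair (k1, k2)
# and an independent factor multiplies the time-constant pair
# (tau1, tau2). Every parameter thus carries relative jitter cv while
# the pair ratios k1/k2 and tau2/tau1 -- and with them the parameter
# invariants and the overshoot shape -- are preserved, as in repeated
# runs of the same extraction. Jittering the four parameters
# independently would instead let the small differences k1 - k2 and
# tau2 - tau1 fluctuate by several hundred percent, producing
# replicate curves of unrelated shape.
jitter_params <- function(params, cv, delta = 1e-4) {
  if (cv == 0) {
    return(params)
  }
  f <- lognormal_factors(2, cv)
  kinetic_params(
    k1 = params$k1 * f[1], k2 = params$k2 * f[1],
    tau1 = params$tau1 * f[2], tau2 = params$tau2 * f[2],
    min_tau_separation = delta
  )
}

#' Generate a synthetic triplicate
#'
#' For each of three replicates: jitter the scenario's true parameters,
#' evaluate the net kinetic curve on the time grid, apply mean-one
#' multiplicative lognormal noise, and (optionally) scale up to
#' raw-like peak areas. Deterministic given the scenario seed; the
#' per-replicate true parameters are attached as the `true_params`
#' attribute for calibration checks.
#'
#' @param scenario a [sim_scenario()].
#' @return A [replicate_set()] of three raw (un-normalized) profiles.
#' @export
generate_replicates <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  truths <- vector("list", 3)
  profiles <- lapply(1:3, function(i) {
    local_seed(scenario$seed + i - 1L, {
      p <- jitter_params(scenario$true_params, scenario$param_jitter_cv)
      truths[[i]] <<- p
      y <- net_conc(p, scenario$time_grid)
      y <- y * lognormal_factors(length(y), scenario$obs_noise_cv)
      if (!is.null(scenario$raw_scale)) y <- y * scenario$raw_scale
      extraction_profile(
        compound = scenario$compound, condition = scenario$condition,
        replicate = i, times = scenario$time_grid, areas = y
      )
    })
  })
  out <- replicate_set(profiles)
  attr(out, "true_params") <- truths
  out
}

preset_catalog <- function() {
  path <- system.file("extdata", "compound_presets.csv", package = "spmekin")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Catalog of simulation presets from published triplicate fits
#'
#' One scenario per compound/matrix/temperature row of the summary
#' table of fitted parameters for flavor esters in an alcoholic
#' beverage (30/40/60 \eqn{^\circ}C) and chewing gum (60
#' \eqn{^\circ}C). Amplitudes are normalized so the plateau
#' `k1 - k2 = 1` (raw amplitudes divided by their difference); time
#' constants are used as printed. Beverage presets use
#' [beverage_grid()], gum presets [gum_grid()]; rows whose grid ends
#' before `3 * tau2` (slow, high-`tau2` compounds) are flagged
#' truncated.
#'
#' These rows are simulation presets and consistency fixtures only:
#' they describe fits to unavailable raw chromatographic data and are
#' never refitting targets.
#'
#' @param seed seed given to every scenario (default 1).
#' @return Named list of [sim_scenario()]s, e.g.
#'   `"ethyl_octanoate_40C"`, `"sugar_free_ethyl_butanoate_60C"`. Each
#'   carries the source row (printed `W`, `F`, RSDs, RMSE and raw
#'   amplitudes) as its `reference` field.
#' @export
preset_scenarios <- function(seed = 1L) {
  cat_df <- preset_catalog()
  scenarios <- lapply(seq_len(nrow(cat_df)), function(i) {
    row <- cat_df[i, ]
    cinf <- row$k1 - row$k2
    params <- kinetic_params(
      k1 = row$k1 / cinf, k2 = row$k2 / cinf,
      tau1 = row$tau1, tau2 = row$tau2
    )
    grid <- if (row$matrix == "chewing gum") gum_grid() else beverage_grid()
    sc <- sim_scenario(
      true_params = params, time_grid = grid, seed = seed,
      compound = row$compound,
      condition = sprintf("%s %d C", row$matrix, row$temp_c),
      truncated = max(grid) < 3 * row$tau2
    )
    sc$reference <- as.list(row)
    sc
  })
  names(scenarios) <- cat_df$name
  scenarios
}
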