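# Shared fixtures: parameter sets, synthetic replicate builders, and a
# fit configuration suitable for well-separated toy amplitudes.

# Hand-checkable parameter set: t_max = 20*ln(4), C_max = 1.125, Cinf = 1.
toy_params <- function() kinetic_params(k1 = 2, k2 = 1, tau1 = 10, tau2 = 20)

# Stiff parameter set in the regime the published fits occupy
# (amplitudes ~174x the plateau, time constants ~1% apart).
stiff_params <- function() {
  kinetic_params(k1 = 174.2, k2 = 173.2, tau1 = 58.30, tau2 = 59.08)
}

# Default amplitude bounds exclude small-amplitude solutions; toy
# parameters (k2 ~ plateau) need the lower bound opened up.
toy_config <- function(...) {
  fit_config(
    bounds = list(
      cinf = c(1e-4, 10), k2 = c(1e-3, 500),
      tau1 = c(0.05, 1500), dtau = c(1e-9, 3000)
    ),
    ...
  )
}

dense_grid <- function() c(2, 5, 10, 15, 20, 30, 45, 60, 90, 120)

# Triplicate with per-replicate tau scaling and multiplicative noise;
# explicit construction used where generate_replicates()'s jitter
# structure would get in the way.
make_tau_shifted_set <- function(params, tau_mults, grid, noise_sd, seed) {
  profs <- lapply(1:3, function(i) {
    p <- kinetic_params(
      params$k1, params$k2,
      params$tau1 * tau_mults[i], params$tau2 * tau_mults[i]
    )
    set.seed(seed + i)
    y <- net_conc(p, grid) * exp(stats::rnorm(length(grid), 0, noise_sd))
    extraction_profile("compound", "cond", i, grid, y)
  })
  replicate_set(profs)
}

# Draw a random well-posed parameter set with an interior peak.
random_overshoot_params <- function() {
  repeat {
    k2 <- stats::runif(1, 0.5, 300)
    cinf <- stats::runif(1, 0.2, 5)
    tau1 <- stats::runif(1, 2, 200)
    tau2 <- tau1 * stats::runif(1, 1.001, 3)
    p <- tryCatch(
      kinetic_params(k2 + cinf, k2, tau1, tau2),
      error = function(e) NULL
    )
    if (!is.null(p) && has_overshoot(p)) {
      return(p)
    }
  }
}

# Numeric peak oracle, independent of the closed form: golden-section
# maximization of the net curve over [0, 20 * tau2].
numeric_peak <- function(params) {
  stats::optimize(
    function(t) net_conc(params, t),
    interval = c(0, 20 * params$tau2),
    maximum = TRUE, tol = 1e-10 * params$tau2
  )
}
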