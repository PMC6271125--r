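test_that("initial tau ranges follow the tabulated selection rules", {
  expect_equal(initial_tau_range(10), c(4, 9))
  expect_equal(initial_tau_range(20), c(9, 14))
  expect_equal(initial_tau_range(60), c(30, 40))
  expect_equal(initial_tau_range(4), c(1, 3))
  # linear interpolation between tabulated peak times
  expect_equal(initial_tau_range(15), c(6.5, 11.5))
  # clamped outside the tabulated span
  expect_equal(initial_tau_range(1), c(1, 3))
  expect_equal(initial_tau_range(1000), c(100, 370))
  expect_error(initial_tau_range(0), "positive")
  expect_error(initial_tau_range(-5), "positive")
})

test_that("starting parameters imply the observed plateau", {
  sc <- sim_scenario(stiff_params(),
    obs_noise_cv = 0, param_jitter_cv = 0, seed = 1
  )
  profile <- normalize_profile(generate_replicates(sc)$profiles[[1]])
  cfg <- fit_config(seed = 5)
  set.seed(11)
  for (i in 1:20) {
    start <- initial_params(profile, cfg)
    c_last <- profile$areas[length(profile$areas)]
    expect_equal(start$k1 - start$k2, c_last)
    m <- start$k1 / c_last
    expect_gte(m, 50)
    expect_lte(m, 200)
    # observed peak at t = 90 on this grid: tabulated range (45, 80)
    expect_gte(start$tau1, 45)
    expect_lte(start$tau2, 80 * (1 + 2e-4))
    expect_lt(start$tau1, start$tau2)
  }
  # identical draws under an identical RNG state
  set.seed(42)
  a <- initial_params(profile, cfg)
  set.seed(42)
  b <- initial_params(profile, cfg)
  expect_identical(a, b)
})

test_that("the weighted objective upweights only the peak sample", {
  p <- toy_params()
  times <- c(5, 10, 20, 30, 45, 60, 90)
  truth <- net_conc(p, times)
  exact <- extraction_profile("c", "x", 1, times, truth, normalized = FALSE)
  for (W in c(1, 10, 250)) {
    expect_equal(weighted_objective(p, exact, W), 0)
  }

  y <- truth * c(1.02, 0.99, 1.01, 0.98, 1.03, 1, 0.99)
  noisy <- extraction_profile("c", "x", 1, times, y)
  r2 <- (net_conc(p, times) - y)^2
  ipk <- which.max(y)
  expect_equal(weighted_objective(p, noisy, 1), sum(r2))
  for (W in c(7, 100)) {
    expect_equal(
      weighted_objective(p, noisy, W),
      sum(r2) + (W - 1) * r2[ipk]
    )
  }
  expect_error(weighted_objective(p, noisy, 0.5), "W must be >= 1")
})

test_that("rmse and rsd follow their definitions", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1.1, 1.9), c(1, 2)), 0.1)
  expect_equal(rmse(c(0.3, 0, 0), c(0, 0, 0)), sqrt(0.09 / 3))
  expect_error(rmse(1:3, 1:4), "equal length")

  expect_equal(rsd(c(1, 1, 1)), 0)
  expect_equal(rsd(c(9, 10, 11)), 10)
  expect_equal(rsd(c(47.96, 47.96, 47.96)), 0)
  expect_error(rsd(c(-1, 1)), "zero mean")
  expect_error(rsd(5), "at least two")
})

test_that("noise-free profiles are recovered to within 0.1 percent", {
  sc <- sim_scenario(toy_params(),
    time_grid = dense_grid(),
    obs_noise_cv = 0, param_jitter_cv = 0, seed = 3
  )
  profile <- normalize_profile(generate_replicates(sc)$profiles[[1]])
  fit <- fit_replicate(profile, W = 1, toy_config(seed = 4))
  div <- profile$norm_divisor
  expect_true(fit$converged)
  expect_lt(fit$rmse, 1e-6)
  expect_equal(fit$params$k1 * div, 2, tolerance = 1e-3)
  expect_equal(fit$params$k2 * div, 1, tolerance = 1e-3)
  expect_equal(fit$params$tau1, 10, tolerance = 1e-3)
  expect_equal(fit$params$tau2, 20, tolerance = 1e-3)
})

test_that("fits at realistic noise levels track the noise scale", {
  sc <- sim_scenario(stiff_params(),
    obs_noise_cv = 0.03, param_jitter_cv = 0, seed = 8
  )
  set <- normalize_set(generate_replicates(sc))
  fit <- fit_replicate(set$profiles[[1]], W = 1, fit_config(seed = 2))
  expect_true(fit$converged)
  expect_gt(fit$rmse, 0.005)
  expect_lt(fit$rmse, 0.06)
})

test_that("fitting is deterministic given the configuration seed", {
  sc <- sim_scenario(stiff_params(), seed = 5)
  profile <- normalize_profile(generate_replicates(sc)$profiles[[2]])
  cfg <- fit_config(seed = 9)
  f1 <- fit_replicate(profile, W = 12, cfg)
  f2 <- fit_replicate(profile, W = 12, cfg)
  expect_identical(unlist(f1$params), unlist(f2$params))
  expect_identical(f1$objective, f2$objective)
})

test_that("amplitudes are scale-equivariant and time constants scale-free", {
  sc <- sim_scenario(stiff_params(), seed = 6)
  raw <- generate_replicates(sc)$profiles[[1]]
  scaled <- raw
  scaled$areas <- raw$areas * 1024 # power of two: exact rescaling
  cfg <- fit_config(seed = 3)
  f1 <- fit_replicate(raw, W = 5, cfg)
  f2 <- fit_replicate(scaled, W = 5, cfg)
  expect_equal(f2$params$k1 / f1$params$k1, 1024, tolerance = 1e-6)
  expect_equal(f2$params$k2 / f1$params$k2, 1024, tolerance = 1e-6)
  expect_equal(f2$params$tau1, f1$params$tau1, tolerance = 1e-6)
  expect_equal(f2$params$tau2, f1$params$tau2, tolerance = 1e-6)
  expect_equal(f2$rmse, f1$rmse, tolerance = 1e-6)
})

test_that("raising W never worsens the fit at the peak sample", {
  sc <- sim_scenario(stiff_params(), seed = 1)
  profile <- normalize_profile(generate_replicates(sc)$profiles[[1]])
  cfg <- fit_config(seed = 2)
  ipk <- which.max(profile$areas)
  r2 <- vapply(c(1, 10, 100, 1000), function(W) {
    fit <- fit_replicate(profile, W, cfg)
    (net_conc(fit$params, profile$times[ipk]) - profile$areas[ipk])^2
  }, 0)
  expect_true(all(diff(r2) <= 1e-12))
})

test_that("profiles without an interior peak are flagged", {
  # pure saturation data: no overshoot to fit
  times <- dense_grid()
  y <- 1 - exp(-times / 30)
  profile <- extraction_profile("c", "x", 1, times, y)
  fit <- fit_replicate(normalize_profile(profile), W = 1, fit_config(seed = 2))
  expect_false(observed_peak(profile)$interior)
  expect_true(
    fit$no_interior_peak || peak_time(fit$params) > max(times)
  )
})

test_that("fits require at least five samples", {
  p <- extraction_profile("c", "x", 1, c(1, 5, 10, 20), c(0.2, 0.6, 1.1, 1))
  expect_error(
    fit_replicate(normalize_profile(p), 1, fit_config(seed = 1)),
    "at least 5"
  )
})

test_that("fit configurations round-trip through the key-value file", {
  cfg <- fit_config(
    k_init_range = c(60, 150), multistart_count = 4,
    ridge_tolerance = 0.1, seed = 77
  )
  path <- tempfile(fileext = ".yaml")
  write_fit_config(cfg, path)
  back <- read_fit_config(path)
  expect_equal(back$k_init_range, cfg$k_init_range)
  expect_equal(back$bounds, cfg$bounds)
  expect_equal(back$multistart_count, cfg$multistart_count)
  expect_equal(back$ridge_tolerance, cfg$ridge_tolerance)
  expect_equal(back$seed, cfg$seed)

  noseed <- tempfile(fileext = ".yaml")
  writeLines("multistart_count: 4", noseed)
  expect_error(read_fit_config(noseed), "seed")
})

test_that("configuration bounds are validated", {
  expect_error(fit_config(multistart_count = 0))
  expect_error(
    fit_config(bounds = list(
      cinf = c(1, 0.5), k2 = c(20, 500),
      tau1 = c(0.05, 1500), dtau = c(1e-9, 3000)
    )),
    "cinf"
  )
})
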