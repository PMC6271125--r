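test_that("zero noise and jitter reproduce the model curve exactly", {
  sc <- sim_scenario(toy_params(),
    time_grid = dense_grid(),
    obs_noise_cv = 0, param_jitter_cv = 0, seed = 7
  )
  set <- generate_replicates(sc)
  truth <- net_conc(toy_params(), dense_grid())
  for (p in set$profiles) {
    expect_equal(p$areas, truth)
  }
  expect_identical(
    set$profiles[[1]]$areas,
    set$profiles[[2]]$areas
  )
})

test_that("generation is deterministic and written CSVs are byte-identical", {
  sc <- sim_scenario(stiff_params(), seed = 11)
  a <- generate_replicates(sc)
  b <- generate_replicates(sc)
  for (i in 1:3) expect_identical(a$profiles[[i]]$areas, b$profiles[[i]]$areas)

  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_profiles(a, f1)
  write_profiles(generate_replicates(sc), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("raw_scale emits raw-like peak areas", {
  sc <- sim_scenario(stiff_params(), raw_scale = 5e7, seed = 2)
  sc0 <- sim_scenario(stiff_params(), seed = 2)
  raw <- generate_replicates(sc)
  norm <- generate_replicates(sc0)
  expect_equal(
    raw$profiles[[1]]$areas,
    norm$profiles[[1]]$areas * 5e7
  )
})

test_that("jittered parameters keep every invariant and the stated cv", {
  sc <- sim_scenario(stiff_params(), param_jitter_cv = 0.05, seed = 1)
  k1s <- numeric(0)
  t1s <- numeric(0)
  for (s in 1:60) {
    sc$seed <- s
    truths <- attr(generate_replicates(sc), "true_params")
    for (p in truths) {
      expect_s3_class(p, "kinetic_params")
      expect_gt(p$k1, p$k2)
      expect_lt(p$tau1, p$tau2)
      # pair ratios preserved by the paired jitter factors
      expect_equal(p$k1 / p$k2, stiff_params()$k1 / stiff_params()$k2)
      k1s <- c(k1s, p$k1)
      t1s <- c(t1s, p$tau1)
    }
  }
  # empirical cv of each jittered parameter ~ 5 percent
  expect_equal(stats::sd(k1s) / mean(k1s), 0.05, tolerance = 0.25)
  expect_equal(stats::sd(t1s) / mean(t1s), 0.05, tolerance = 0.25)
})

test_that("ensemble mean of noisy areas converges to the model curve", {
  sc <- sim_scenario(stiff_params(),
    obs_noise_cv = 0.05, param_jitter_cv = 0, seed = 1
  )
  grid <- sc$time_grid
  truth <- net_conc(stiff_params(), grid)
  sums <- matrix(0, length(grid), 0)
  for (s in 1:300) {
    sc$seed <- s
    set <- generate_replicates(sc)
    sums <- cbind(sums, vapply(set$profiles, `[[`, grid, "areas"))
  }
  n <- ncol(sums) # 900 replicates
  means <- rowMeans(sums)
  se <- apply(sums, 1, stats::sd) / sqrt(n)
  expect_true(all(abs(means - truth) <= 3 * se + 1e-12))
})

test_that("the fitted parameters recover the generator's jitter scale", {
  # identifiable truth: amplitudes comparable to the plateau, noise far
  # below the jitter, so refitted spread reflects the injected 5 percent
  j <- 0.05
  cfg <- toy_config(seed = 2, multistart_count = 4)
  rsds <- matrix(NA_real_, 12, 2)
  for (s in seq_len(nrow(rsds))) {
    sc <- sim_scenario(toy_params(),
      time_grid = dense_grid(),
      obs_noise_cv = 1e-3, param_jitter_cv = j, seed = 100 + s
    )
    set <- generate_replicates(sc)
    fits <- lapply(set$profiles, fit_replicate, W = 1, config = cfg)
    rsds[s, 1] <- rsd(vapply(fits, function(f) f$params$k1, 0))
    rsds[s, 2] <- rsd(vapply(fits, function(f) f$params$tau1, 0))
  }
  # mean RSD across triplicate batches ~ 100 j within sampling error
  expect_equal(mean(rsds[, 1]), 100 * j, tolerance = 0.45)
  expect_equal(mean(rsds[, 2]), 100 * j, tolerance = 0.45)
})

test_that("scenario validation guards the grid and noise settings", {
  expect_error(
    sim_scenario(stiff_params(), time_grid = c(5, 10, 20, 30, 45)),
    "truncated = TRUE"
  )
  expect_silent(
    sim_scenario(stiff_params(),
      time_grid = c(5, 10, 20, 30, 45),
      truncated = TRUE
    )
  )
  expect_error(sim_scenario(toy_params(), obs_noise_cv = -0.1), ">= 0")
  expect_error(
    sim_scenario(toy_params(), time_grid = c(0, 5, 10, 20, 30)),
    "positive"
  )
})

test_that("preset scenarios reproduce the published parameter table", {
  presets <- preset_scenarios(seed = 1)
  expect_length(presets, 24)

  ah <- presets[["allyl_hexanoate_30C"]]
  expect_equal(ah$true_params$tau1, 47.96)
  expect_equal(ah$true_params$tau2, 48.40)
  expect_equal(equilibrium_conc(ah$true_params), 1)
  expect_equal(ah$true_params$k1, 6.23e9 / 5e7, tolerance = 1e-6)

  eb <- presets[["sugar_free_ethyl_butanoate_60C"]]
  expect_equal(eb$true_params$tau1, 6.17)
  expect_equal(eb$true_params$tau2, 6.23)
  expect_equal(eb$time_grid, gum_grid())

  eo <- presets[["ethyl_octanoate_40C"]]
  expect_equal(eo$true_params$k1, 174.2)
  expect_equal(eo$true_params$k2, 173.2)
  expect_equal(eo$time_grid, beverage_grid())
  expect_false(eo$truncated)

  for (p in presets) {
    expect_true(has_overshoot(p$true_params))
    expect_equal(equilibrium_conc(p$true_params), 1)
    # normalized amplitudes sit in the published stiff range
    expect_gt(p$true_params$k1, 60)
    expect_lt(p$true_params$k1, 320)
    expect_identical(
      p$truncated,
      max(p$time_grid) < 3 * p$true_params$tau2
    )
  }
  # slow compounds cannot reach equilibrium on the 300-minute grid
  expect_true(presets[["ethyl_decanoate_40C"]]$truncated)
  expect_true(presets[["ethyl_lauroate_60C"]]$truncated)
})
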