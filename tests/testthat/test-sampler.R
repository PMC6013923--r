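test_that("warm-up points are feasible and reproducible", {
  m <- segment_model()
  W <- generate_warmup(m, n_warmup = 40, seed = 5)
  expect_equal(dim(W), c(2, 40))
  expect_true(all(W >= -1e-9 & W <= 1 + 1e-9))
  expect_equal(W["SRC", ], W["SNK", ], tolerance = 1e-10)
  # fixed seed gives bit-identical warm-up
  expect_identical(W, generate_warmup(m, n_warmup = 40, seed = 5))
  expect_false(identical(W, generate_warmup(m, n_warmup = 40, seed = 6)))

  expect_error(generate_warmup(m, n_warmup = 1, seed = 1),
               "null-space dimension")
})

test_that("warm-up on the constrained fixture satisfies steady state", {
  m <- apply_diet(build_fixture_model(),
                  compute_uptake_bounds(builtin_diets()[["FAT10"]]))
  W <- generate_warmup(m, n_warmup = 30, seed = 2)
  S <- stoichiometric_matrix(m, sparse = FALSE)
  expect_lt(max(abs(S %*% W)), 1e-6)
  lb <- lower_bounds(m); ub <- upper_bounds(m)
  expect_true(all(W >= lb - 1e-9 & W <= ub + 1e-9))
})

test_that("ACHR samples a segment uniformly", {
  m <- segment_model()
  fs <- achr_sample(m, sampler_config(n_points = 400, steps_per_point = 20,
                                      seed = 31, optimality_fraction = 0))
  v <- fs$samples["SRC", ]
  # equality coupling holds to numerical precision
  expect_lt(max(abs(fs$samples["SRC", ] - fs$samples["SNK", ])), 1e-8)
  # uniform on [0, 1]: mean 0.5 within 3 standard errors (se of U(0,1) mean,
  # inflated for chain autocorrelation via effective n = n/5)
  se <- 1 / sqrt(12) / sqrt(length(v) / 5)
  expect_lt(abs(mean(v) - 0.5), 3 * se)
  expect_true(all(v >= -1e-9 & v <= 1 + 1e-9))
})

test_that("ACHR is deterministic given (model, config, seed)", {
  m <- toy_polytope_model()
  cfg <- sampler_config(n_points = 50, steps_per_point = 10, seed = 77,
                        optimality_fraction = 0)
  fs1 <- achr_sample(m, cfg)
  fs2 <- achr_sample(m, cfg)
  expect_identical(fs1$samples, fs2$samples)
  fs3 <- achr_sample(m, sampler_config(n_points = 50, steps_per_point = 10,
                                       seed = 78, optimality_fraction = 0))
  expect_false(identical(fs1$samples, fs3$samples))
})

test_that("ACHR marginals match a rejection-sampling oracle on the toy polytope", {
  m <- toy_polytope_model()
  n <- 1000
  # KS assumes independent draws: thin the chain (50 steps) and use a
  # moderate warm-up matrix so direction proposals span the polytope
  fs <- achr_sample(m, sampler_config(n_points = n, steps_per_point = 50,
                                      n_warmup = 50,
                                      seed = 13, optimality_fraction = 0))
  ref <- toy_polytope_rejection(n, seed = 14)
  crit <- sqrt(-log(0.01 / 2) / 2) * sqrt((n + n) / (n * n))
  for (k in 1:3) {
    D <- suppressWarnings(
      stats::ks.test(fs$samples[k, ], ref[k, ])$statistic)
    expect_lt(unname(D), crit)
  }
})

test_that("every recorded fixture sample is steady-state valid within bounds", {
  m <- apply_diet(build_fixture_model(),
                  compute_uptake_bounds(builtin_diets()[["FISH44"]]))
  fs <- achr_sample(m, sampler_config(n_points = 60, steps_per_point = 40,
                                      seed = 3))
  S <- stoichiometric_matrix(m, sparse = FALSE)
  expect_lt(max(abs(S %*% fs$samples)), 1e-6)
  lb <- lower_bounds(m); ub <- upper_bounds(m)
  expect_true(all(fs$samples >= lb - 1e-9))
  expect_true(all(fs$samples <= ub + 1e-9))
  # optimality constraint respected
  opt <- fba_max_atp(m)$objective_value
  expect_true(all(fs$samples["DM_atp_c", ] >= 0.99 * opt - 1e-6))
})

test_that("a zero-dimensional polytope returns its single point with a warning", {
  m <- chain_model(cap = 1)
  m <- set_bounds(m, "EX_A_c", lower = -1, upper = -1)  # forced uptake
  expect_warning(
    fs <- achr_sample(m, sampler_config(n_points = 10, steps_per_point = 5,
                                        seed = 1, optimality_fraction = 0)),
    "zero dimension")
  expect_equal(ncol(fs$samples), 1)
  expect_equal(unname(fs$samples[, 1]), c(-1, 1, 1), tolerance = 1e-8)
})

test_that("sampler configuration is validated", {
  expect_error(sampler_config(n_points = 0), "positive integer")
  expect_error(sampler_config(steps_per_point = -3), "positive integer")
  expect_error(sampler_config(optimality_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sampler_config(tolerance = 0), "positive")
})
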