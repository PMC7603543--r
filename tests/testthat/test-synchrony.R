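test_that("population mean trace averages rows sample by sample", {
  expect_equal(population_mean_trace(rbind(c(1, 2), c(3, 4))), c(2, 3))
  one <- matrix(sin(1:20), nrow = 1)
  expect_equal(population_mean_trace(one), sin(1:20))
  sym <- rbind(rep(10, 5), rep(-10, 5))
  expect_equal(population_mean_trace(sym), rep(0, 5))
  expect_error(population_mean_trace(matrix(numeric(0), nrow = 0)),
               "empty_traces")
})

test_that("temporal variance is the uncentred second moment minus squared mean", {
  expect_equal(temporal_variance(rep(3.7, 10)), 0)
  expect_equal(temporal_variance(c(0, 2)), 1)
  x <- rnorm(50)
  expect_equal(temporal_variance(x + 123.4), temporal_variance(x),
               tolerance = 1e-9)
  # population-style normalisation (divide by T, not T-1)
  expect_equal(temporal_variance(x), mean(x^2) - mean(x)^2)
  expect_error(temporal_variance(3), "too_few_samples")
})

test_that("chi-squared is 1 for identical traces, 0 for antiphase pairs, and bounded", {
  base <- sin(seq(0, 6 * pi, length.out = 200)) - 60
  ident <- matrix(rep(base, each = 12), nrow = 12)
  r1 <- chi_squared(ident)
  expect_equal(r1$chi_squared, 1, tolerance = 1e-12)
  expect_equal(r1$chi, 1, tolerance = 1e-12)
  expect_false(r1$degenerate)

  anti <- rbind(base - mean(base), -(base - mean(base)))
  r0 <- chi_squared(anti)
  expect_equal(r0$chi_squared, 0, tolerance = 1e-12)

  set.seed(404)
  for (k in 1:1000) {
    n <- sample(2:8, 1)
    tt <- sample(2:30, 1)
    m <- matrix(rnorm(n * tt, sd = runif(1, 0.1, 20)), nrow = n)
    x2 <- chi_squared(m)$chi_squared
    expect_gte(x2, 0)
    expect_lte(x2, 1 + 1e-12)
  }
})

test_that("all-constant trace matrices are flagged degenerate, not errors", {
  m <- matrix(-65, nrow = 4, ncol = 10)
  r <- chi_squared(m)
  expect_true(r$degenerate)
  expect_equal(r$chi_squared, 0)
  expect_error(chi_squared(matrix(1:5, nrow = 1)), "too_few_neurons")
})

test_that("chi-squared matches a brute-force double-loop evaluation", {
  set.seed(55)
  for (k in 1:25) {
    m <- matrix(rnorm(5 * 20, mean = -60, sd = 8), nrow = 5)
    got <- chi_squared(m)$chi_squared
    want <- brute_force_chi2(m)
    expect_lt(abs(got - want) / abs(want), 1e-12)
  }
})

test_that("chi-squared is invariant under neuron permutations", {
  set.seed(77)
  m <- matrix(rnorm(10 * 40), nrow = 10)
  x2 <- chi_squared(m)$chi_squared
  for (k in 1:10) {
    expect_equal(chi_squared(m[sample(10), ])$chi_squared, x2,
                 tolerance = 1e-12)
  }
})

test_that("independent traces give chi-squared near 1/N at both tested sizes", {
  tt <- 1e4
  set.seed(2024)
  for (n in c(10, 100)) {
    m <- matrix(rnorm(n * tt), nrow = n)
    x2 <- chi_squared(m)$chi_squared
    se <- sqrt(2 / tt) / n   # sd of the variance-of-mean estimator over T samples
    expect_lt(abs(x2 - 1 / n), 5 * se)
    # scaled form: N * chi^2 -> 1
    expect_lt(abs(n * x2 - 1), 5 * sqrt(2 / tt) * 2)
  }
})

test_that("weight sweep overrides every connection and labels results", {
  cfg <- make_fixture(2, 12, seed = 19, duration = 100)
  res <- weight_sweep(cfg, weights = 7, seed = 19, discard_ms = 20)
  expect_equal(nrow(res), 2)   # one row per group for a single weight
  expect_identical(res$weight_mV, c(7, 7))
  expect_identical(sort(res$group), sort(cfg$groups$name))
  expect_true(all(res$chi_squared >= 0 & res$chi_squared <= 1 + 1e-12))
  expect_equal(res$chi, sqrt(res$chi_squared))

  # restricting groups restricts rows
  res1 <- weight_sweep(cfg, weights = c(1, 7), groups = "RS_e1", seed = 19,
                       discard_ms = 20)
  expect_equal(nrow(res1), 2)
  expect_true(all(res1$group == "RS_e1"))
  expect_error(weight_sweep(cfg, weights = numeric(0)), "empty_weights")
  expect_error(weight_sweep(cfg, weights = 5, groups = "nope"), "unknown group")
})

test_that("constant-trace groups are flagged degenerate and quiescent sweeps complete", {
  # a recording whose members all sit at rest: denominator of the measure
  # is zero, reported as chi^2 = 0 with the flag rather than an error
  rec <- structure(list(v = matrix(-65, nrow = 6, ncol = 80),
                        groups = "A", group_of = rep(1L, 6), duration = 80),
                   class = "recording_set")
  res <- run_synchrony(rec, discard_ms = 20)
  expect_true(res$degenerate_flag)
  expect_equal(res$chi_squared, 0)

  # a zero-weight, zero-noise sweep still completes with in-range values
  cfg <- quiet_config(n_per_group = 4, weight = 0, sigma = 0,
                      g_init_max = 0, duration = 80)
  res2 <- weight_sweep(cfg, weights = 0, seed = 1, discard_ms = 20)
  expect_equal(nrow(res2), 2)
  expect_true(all(res2$chi_squared >= 0 & res2$chi_squared <= 1 + 1e-12))
})

test_that("sweep results are reproducible for a fixed base seed", {
  cfg <- make_fixture(2, 10, seed = 23, duration = 80)
  r1 <- weight_sweep(cfg, weights = c(1, 31), seed = 23, discard_ms = 20)
  r2 <- weight_sweep(cfg, weights = c(1, 31), seed = 23, discard_ms = 20)
  expect_identical(r1, r2)
})
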