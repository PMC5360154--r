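test_that("series container enforces strictly increasing time", {
  expect_error(observation_series(c(3, 2, 1), c(1, 2, 3)), "increasing")
  expect_error(observation_series(c(1, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(observation_series(1, 1), "two points")
  s <- observation_series(c(1, 2), c(5, 6), rank = 2, treatment = "M")
  expect_s3_class(s, "observation_series")
})

test_that("normalization divides by the endpoint maxima and inverts", {
  s <- observation_series(c(10, 20, 40), c(1, 2, 4))
  n <- normalize_series(s)
  expect_equal(n$series$y, c(0.25, 0.5, 1))
  expect_equal(n$series$ts, c(0.25, 0.5, 1))
  expect_equal(n$anchors$y_max, 4)
  expect_equal(n$anchors$ts_max, 40)
  # denormalizing restores the original series
  expect_equal(n$series$y * n$anchors$y_max, s$y)
  expect_equal(n$series$ts * n$anchors$ts_max, s$ts)
  expect_error(normalize_series(observation_series(c(1, 2), c(0, 0))),
               "positive")
})

test_that("blade-extension fit recovers known parameters from clean data", {
  p <- leaf_extension_params(3, "H")
  s <- generate_synthetic_series("leaf", p, seq(50, 700, by = 25))
  f <- fit_leaf_logistic(s)
  expect_true(f$converged)
  expect_lt(max(rel_err(f$params[c("y_m", "ts_0", "b")],
                        p[c("y_m", "ts_0", "b")])), 1e-4)
  expect_lt(f$rss, 1e-12)
})

test_that("blade-extension fit is robust to measurement noise", {
  p <- leaf_extension_params(3, "H")
  grid <- seq(50, 700, by = 25)
  y_m_hat <- vapply(1:50, function(i) {
    s <- generate_synthetic_series("leaf", p, grid, noise_sd = 0.1,
                                   seed = 100 + i)
    f <- fit_leaf_logistic(s)
    if (f$converged) f$params$y_m else NA_real_
  }, numeric(1))
  expect_lt(abs(stats::median(y_m_hat, na.rm = TRUE) - p$y_m) / p$y_m, 0.05)
})

test_that("degenerate constant series are flagged, not errored", {
  s <- observation_series(1:10, rep(2, 10))
  f <- fit_leaf_logistic(s)
  expect_false(f$converged)
  expect_true(f$degenerate)
  f2 <- fit_leaf_area_curve(s)
  expect_false(f2$converged)
  expect_true(f2$degenerate)
})

test_that("decreasing positive-slope extension rows are also recoverable", {
  p <- leaf_extension_params(2, "L")  # b = 62.99, a sharp decreasing step
  s <- generate_synthetic_series("leaf", p, seq(10, 700, by = 10))
  f <- fit_leaf_logistic(s)
  expect_true(f$converged)
  expect_lt(max(rel_err(f$params[c("y_m", "ts_0", "b")],
                        p[c("y_m", "ts_0", "b")])), 1e-3)
})

test_that("double-logistic fit locates the plant-level transition point", {
  p <- plant_dry_mass_params("H")
  s <- generate_synthetic_series("drymass2", p, seq(0, 1, by = 0.01))
  f <- fit_double_logistic(s)
  expect_true(f$converged)
  expect_lt(abs(f$params$ts_tr - 0.38), 0.05)
  expect_lt(max(rel_err(f$params$lower, p$lower)), 1e-3)
  expect_lt(max(rel_err(f$params$upper, p$upper)), 1e-3)
})

test_that("the double logistic nests the single logistic in rss", {
  # data generated from a single-branch curve
  p <- rank_dry_mass_params(2, "M")
  s <- generate_synthetic_series("drymass", p, seq(0, 1, by = 0.02),
                                 noise_sd = 0.02, seed = 7)
  f_single <- fit_normalized_logistic(s)
  f_double <- fit_double_logistic(s)
  expect_lte(f_double$rss, f_single$rss + 1e-12)
  expect_equal(f_double$rss_single, f_single$rss)
})

test_that("double-logistic preconditions reject unusable input", {
  expect_error(fit_double_logistic(observation_series(1:8 / 10, 1:8)),
               "at least 9")
  expect_error(
    fit_double_logistic(observation_series(seq(10, 100, 10), 1:10)),
    "normalized")
})

test_that("leaf-area fit recovers known parameters and the midpoint", {
  p <- leaf_area_params("M")
  s <- generate_synthetic_series("leafarea", p, seq(0, 700, by = 10))
  f <- fit_leaf_area_curve(s)
  expect_true(f$converged)
  expect_lt(max(rel_err(f$params[c("la_0", "la_max", "ts_m", "b")],
                        unclass(p)[c("la_0", "la_max", "ts_m", "b")])),
            1e-3)
  # midpoint identity survives the fit round trip
  ph <- leaf_area_params("H")
  sh <- generate_synthetic_series("leafarea", ph, seq(0, 700, by = 10))
  fh <- fit_leaf_area_curve(sh)
  expect_equal(whole_plant_leaf_area(fh$params$ts_m, fh$params),
               fh$params$la_0 + fh$params$la_max / 2)
})

test_that("synthetic series are exact without noise and seed-reproducible", {
  p <- leaf_extension_params(4, "M")
  grid <- seq(20, 600, by = 20)
  s0 <- generate_synthetic_series("leaf", p, grid)
  expect_identical(s0$y, leaf_length(grid, p))
  s1 <- generate_synthetic_series("leaf", p, grid, noise_sd = 0.2, seed = 11)
  s2 <- generate_synthetic_series("leaf", p, grid, noise_sd = 0.2, seed = 11)
  expect_identical(s1$y, s2$y)
  s3 <- generate_synthetic_series("leaf", p, grid, noise_sd = 0.2, seed = 12)
  expect_false(identical(s1$y, s3$y))
  expect_error(generate_synthetic_series("leaf", p, grid, noise_sd = -1),
               "non-negative")
  expect_error(generate_synthetic_series("leaf", p, grid, noise_sd = 0.1),
               "seed")
})

test_that("noise averages to the true curve over many seeds", {
  p <- leaf_extension_params(3, "H")
  ts_probe <- c(246.15, 400)
  sd <- 0.1
  vals <- vapply(1:1000, function(i) {
    generate_synthetic_series("leaf", p, ts_probe, noise_sd = sd,
                              seed = i)$y[1]
  }, numeric(1))
  sem <- sd / sqrt(1000)
  expect_lt(abs(mean(vals) - leaf_length(246.15, p)), 3 * sem)
})
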