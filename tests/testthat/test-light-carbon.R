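test_that("sensor transport is linear in source output and zero when dark", {
  sc <- chamber_scene()
  dark <- chamber_scene(source_output = 0)
  bright <- chamber_scene(source_output = 660)
  p1 <- estimate_sensor_ppfd(sc, n_rays = 5000, seed = 3)
  p0 <- estimate_sensor_ppfd(dark, n_rays = 5000, seed = 3)
  p2 <- estimate_sensor_ppfd(bright, n_rays = 5000, seed = 3)
  expect_identical(p0$ppfd, c(0, 0))
  expect_equal(p2$ppfd, 2 * p1$ppfd)
})

test_that("default calibrated scene reproduces the measured chamber PPFD", {
  est <- estimate_sensor_ppfd(chamber_scene(), n_rays = 3e4, seed = 5)
  expect_equal(mean(est$ppfd), 150, tolerance = 0.1)
  expect_true(all(est$se > 0))
})

test_that("Monte-Carlo standard error shrinks as one over sqrt(rays)", {
  sc <- chamber_scene()
  e1 <- estimate_sensor_ppfd(sc, n_rays = 4000, seed = 9)
  e2 <- estimate_sensor_ppfd(sc, n_rays = 16000, seed = 10)
  expect_equal(e2$se, e1$se / 2, tolerance = 0.35)
})

test_that("sensors outside the box are rejected", {
  expect_error(chamber_scene(sensors = rbind(c(2, 0.3, 0.5))),
               "outside the chamber")
})

test_that("absorbed light respects energy conservation and occlusion", {
  sc <- chamber_scene()
  state <- make_test_plant("M", ranks = 1:3, lengths = 8)
  geo <- export_structure(state)
  absorbed <- per_leaf_absorbed_par(sc, geo, n_rays = 20000, seed = 2)
  total_emitted <- sc$source_output *
    sum(vapply(sc$panels, `[[`, numeric(1), "area"))
  expect_true(all(absorbed$absorbed_umol_s >= 0))
  expect_lt(sum(absorbed$absorbed_umol_s), total_emitted)
  # empty plant: empty map
  empty <- per_leaf_absorbed_par(sc, geo[0, ], n_rays = 5000, seed = 2)
  expect_identical(nrow(empty), 0L)
  # a leaf closely shaded from above absorbs less than when alone
  disk <- function(rank, z) tibble::tibble(
    rank = rank, azimuth_deg = 0, elevation_deg = 0,
    tip_x = 0, tip_y = 0, tip_z = z,
    blade_cx = 0, blade_cy = 0, blade_cz = z,
    normal_x = 0, normal_y = 0, normal_z = 1,
    semi_major_cm = 10, semi_minor_cm = 10)
  sc2 <- chamber_scene(plant_origin = c(0.5, 0.3, 0))
  alone <- per_leaf_absorbed_par(sc2, disk(1L, 40), n_rays = 40000, seed = 4)
  pair <- per_leaf_absorbed_par(sc2, rbind(disk(2L, 40.5), disk(1L, 40)),
                                n_rays = 40000, seed = 4)
  expect_lt(pair$absorbed_umol_s[pair$rank == 1],
            alone$absorbed_umol_s[1])
})

test_that("an overhead panel favours the leaf directly beneath it", {
  panel <- light_panel(c(0.45, 0.25, 1.5), c(0.1, 0, 0), c(0, 0.1, 0),
                       normal = c(0, 0, -1))
  sc <- chamber_scene(panels = list(panel), plant_origin = c(0, 0, 0))
  disk_at <- function(x, y) tibble::tibble(
    rank = 1L, azimuth_deg = 0, elevation_deg = 0,
    tip_x = x * 100, tip_y = y * 100, tip_z = 50,
    blade_cx = x * 100, blade_cy = y * 100, blade_cz = 50,
    normal_x = 0, normal_y = 0, normal_z = 1,
    semi_major_cm = 8, semi_minor_cm = 8)
  under <- per_leaf_absorbed_par(sc, disk_at(0.5, 0.3), n_rays = 30000,
                                 seed = 6)
  corner <- per_leaf_absorbed_par(sc, disk_at(0.05, 0.05), n_rays = 30000,
                                  seed = 6)
  expect_gt(under$absorbed_umol_s, corner$absorbed_umol_s)
})

test_that("leaf photosynthesis follows the limiting-rate closed form", {
  p <- photosynthesis_params()
  # independent oracle: the standard C3 closed form written out here
  oracle <- function(q, tl) {
    f <- function(x25, q10) x25 * q10^((tl - 25) / 10)
    ci <- p$ci_ratio * p$ca
    gs <- f(p$gamma_star25, p$q10_gamma)
    i2 <- p$alpha_q * q
    jmax <- f(p$jmax25, p$q10_jmax)
    j <- ((i2 + jmax) - sqrt((i2 + jmax)^2 - 4 * p$theta * i2 * jmax)) /
      (2 * p$theta)
    wc <- f(p$vcmax25, p$q10_vcmax) * (ci - gs) /
      (ci + f(p$kc25, p$q10_kc) * (1 + p$o2 / f(p$ko25, p$q10_ko)))
    wj <- j * (ci - gs) / (4 * ci + 8 * gs)
    min(wc, wj) - f(p$rd25, p$q10_rd)
  }
  for (q in c(0, 25, 150, 500, 2000)) {
    for (tl in c(10, 18, 25, 30)) {
      expect_equal(net_assimilation(q, tl, p), oracle(q, tl),
                   tolerance = 1e-6)
    }
  }
})

test_that("assimilation is dark respiration at zero light and saturates", {
  p <- photosynthesis_params()
  expect_equal(net_assimilation(0, 25, p), -p$rd25)
  expect_equal(net_assimilation(0, 15, p), -p$rd25 * p$q10_rd^(-1))
  # monotone non-decreasing in light
  a <- net_assimilation(seq(0, 3000, by = 25), 25, p)
  expect_true(all(diff(a) >= -1e-12))
  # saturates at the Rubisco-limited ceiling
  ci <- p$ci_ratio * p$ca
  wc <- p$vcmax25 * (ci - p$gamma_star25) /
    (ci + p$kc25 * (1 + p$o2 / p$ko25))
  expect_equal(net_assimilation(1e6, 25, p), wc - p$rd25, tolerance = 1e-3)
  expect_error(net_assimilation(-5, 25, p), "non-negative")
})

test_that("the daily carbon books balance to machine precision", {
  set.seed(42)
  umol_per_mg <- function(budget) budget$ch2o_per_dm / 30e-3
  for (i in 1:25) {
    state <- make_test_plant("M", ranks = 1:3,
                             lengths = runif(3, 0.5, 12))
    map <- tibble::tibble(rank = 1:3,
                          absorbed_umol_s = runif(3, 0, 2))
    reg <- temperature_regime(runif(1, 5, 25), runif(1, 10, 32))
    budget <- carbon_budget_params(maint25 = runif(1, 0.005, 0.04),
                                   yg = runif(1, 0.5, 0.95),
                                   ch2o_per_dm = runif(1, 0.8, 1.6))
    cb <- daily_carbon_budget(state, map, reg, budget = budget)
    lhs <- cb$gross_umol
    rhs <- cb$resp_maint_umol + cb$resp_growth_umol +
      cb$increment_mg * umol_per_mg(budget)
    expect_lt(abs(lhs - rhs) / max(abs(lhs), abs(rhs), 1e-9), 1e-9)
  }
})

test_that("darkness costs maintenance and gross scales with leaf area", {
  state <- make_test_plant("M", ranks = 1:3, lengths = 6)
  dark_map <- tibble::tibble(rank = 1:3, absorbed_umol_s = c(0, 0, 0))
  cb <- daily_carbon_budget(state, dark_map, regime_preset("M"))
  expect_lt(cb$increment_mg, 0)
  expect_identical(cb$gross_umol, 0)
  # doubling every blade area at fixed per-area flux doubles gross uptake
  map <- tibble::tibble(rank = 1:3, absorbed_umol_s = c(0.5, 0.8, 0.3))
  cb1 <- daily_carbon_budget(state, map, regime_preset("M"))
  state2 <- state
  state2$phytomers$blade_area <- 2 * state2$phytomers$blade_area
  map2 <- map
  map2$absorbed_umol_s <- 2 * map2$absorbed_umol_s
  cb2 <- daily_carbon_budget(state2, map2, regime_preset("M"))
  expect_equal(cb2$gross_umol, 2 * cb1$gross_umol)
})

test_that("carbon mode adds balanced budget columns to the trajectory", {
  traj <- suppressWarnings(
    run_simulation("M", 5, carbon = TRUE, n_rays = 5000, seed = 3))
  pd <- traj$plant_daily
  expect_true(all(c("gross_umol", "resp_maint_umol", "resp_growth_umol",
                    "dmass_mg") %in% names(pd)))
  conv <- carbon_budget_params()$ch2o_per_dm / 30e-3
  for (i in 2:nrow(pd)) {
    expect_equal(pd$gross_umol[i],
                 pd$resp_maint_umol[i] + pd$resp_growth_umol[i] +
                   pd$dmass_mg[i] * conv)
  }
  # identical seed reruns are reproducible
  traj2 <- suppressWarnings(
    run_simulation("M", 5, carbon = TRUE, n_rays = 5000, seed = 3))
  expect_identical(traj$plant_daily, traj2$plant_daily)
})
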