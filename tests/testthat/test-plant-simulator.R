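test_that("leaves appear once per phyllochron crossing", {
  ph <- phenology_params()
  state <- new_plant("M", ph)
  expect_identical(nrow(state$phytomers), 1L)
  state <- initiate_leaves(state, 460, ph)
  expect_identical(nrow(state$phytomers), 7L)  # 1 + floor(460 / 75)
  expect_identical(state$phytomers$rank, 1:7)
  # unchanged thermal time adds nothing
  expect_identical(nrow(initiate_leaves(state, state$ts, ph)$phytomers), 7L)
  h <- initiate_leaves(new_plant("H", ph), 700, ph)
  expect_identical(nrow(h$phytomers), 10L)
  # spiral phyllotaxis
  az <- state$phytomers$azimuth
  expect_equal(az, ((0:6) * 137.5) %% 360)
  state$ts <- 460
  expect_error(initiate_leaves(state, 100, ph), "smaller")
})

test_that("leaf count matches the closed-form phyllochron arithmetic", {
  for (tr in c("H", "M", "L")) {
    inc <- daily_increment(regime_preset(tr))
    traj <- suppressWarnings(run_simulation(tr, 30))
    expect_identical(traj$plant_daily$n_leaves,
                     as.integer(1 + floor((0:30) * inc / 75)))
  }
})

test_that("per-leaf update applies extension curve and allometry", {
  state <- new_plant("H")
  p <- leaf_extension_params(3, "H")
  phyt <- tibble::tibble(rank = 3L, ts_init = 150, azimuth = 275,
                         blade_length = 0, blade_width = 0,
                         petiole_length = 0, blade_area = 0, dry_mass = 0)
  up <- update_leaf(phyt, 246.15, "H")
  expect_equal(up$blade_length, 4.52)
  up2 <- update_leaf(phyt, 1e6, "H")
  expect_equal(up2$blade_length, 9.04, tolerance = 0.01)
  expect_equal(up2$blade_width, up2$blade_length * wlr(3, "H"))
  expect_equal(up2$petiole_length, up2$blade_length * pbr(3, "H"))
  expect_equal(up2$dry_mass, up2$blade_area * lma(3, "H") * 100)
  # running maximum: a longer recorded blade never shrinks
  phyt$blade_length <- 8
  up3 <- update_leaf(phyt, 246.15, "H")
  expect_equal(up3$blade_length, 8)
})

test_that("blade lengths never decrease despite decaying raw curves", {
  # the low-temperature rows with positive slope decay after their step
  traj <- run_simulation("L", 45)
  for (r in unique(traj$leaves_daily$rank)) {
    lens <- traj$leaves_daily$length_cm[traj$leaves_daily$rank == r]
    expect_true(all(diff(lens) >= 0))
  }
})

test_that("trajectories are deterministic and totals never decrease", {
  t1 <- suppressWarnings(run_simulation("H", 30, mode = "empirical"))
  t2 <- suppressWarnings(run_simulation("H", 30, mode = "empirical"))
  expect_identical(t1$plant_daily, t2$plant_daily)
  expect_identical(t1$leaves_daily, t2$leaves_daily)
  for (tr in c("H", "M", "L")) {
    traj <- suppressWarnings(run_simulation(tr, 30, mode = "empirical"))
    pd <- traj$plant_daily
    expect_true(all(diff(pd$total_area_cm2) >= 0))
    expect_true(all(diff(pd$total_mass_mg) >= 0))
    expect_true(all(diff(pd$area_empirical_cm2) >= 0))
    # the empirical dry-mass column reports the fitted curve faithfully
    # (the printed upper branches dip slightly after their vertex, so
    # monotonicity is asserted for the geometric accounting only)
    dflt <- denorm_anchors(1, 30 * daily_increment(regime_preset(tr)))
    expect_equal(pd$mass_empirical,
                 dry_mass(pd$ts, plant_dry_mass_params(tr), dflt))
  }
})

test_that("per-leaf trajectories stay bounded by their maximum length", {
  traj <- run_simulation("M", 30)
  tab <- leaf_extension_table()
  for (r in 1:5) {
    ym <- tab$y_m[tab$treatment == "M" & tab$rank == r]
    lens <- traj$leaves_daily$length_cm[traj$leaves_daily$rank == r]
    expect_true(all(lens <= ym + 1e-9))
  }
})

test_that("zero-day runs return the initial state only", {
  traj <- run_simulation("M", 0)
  expect_identical(nrow(traj$plant_daily), 1L)
  expect_identical(traj$plant_daily$n_leaves, 1L)
  expect_identical(traj$plant_daily$total_area_cm2, 0)
})

test_that("empirical mode reports the whole-plant curves alongside", {
  traj <- suppressWarnings(run_simulation("H", 40, mode = "empirical"))
  pd <- traj$plant_daily
  la <- leaf_area_params("H")
  expect_equal(pd$area_empirical_cm2,
               whole_plant_leaf_area(pd$ts, la))
  # plateau approached at long times
  long <- suppressWarnings(run_simulation("H", 120, mode = "empirical"))
  expect_equal(max(long$plant_daily$area_empirical_cm2), 136,
               tolerance = 1e-6)
})

test_that("mismatched regime preset and treatment is a config error", {
  state <- new_plant("M")
  expect_error(step(state, regime_preset("H")), "config error")
  # an untagged custom regime is allowed with any treatment
  expect_s3_class(step(state, temperature_regime(18, 22)), "plant_state")
})

test_that("ranks beyond the parameter table extend via the fallback curve", {
  traj <- suppressWarnings(run_simulation("H", 30))
  last <- traj$leaves_daily[traj$leaves_daily$day == 30, ]
  expect_identical(nrow(last), 10L)
  expect_true(all(last$length_cm > 0))
  # fallback reuses the rank-5 curve shifted by initiation time, so a later
  # rank is never longer than the rank-5 leaf itself
  expect_true(all(last$length_cm[last$rank > 5] <=
                    last$length_cm[last$rank == 5]))
})

test_that("structure export places blades on the phyllotactic spiral", {
  state <- make_test_plant("M", ranks = 1:4, lengths = 5)
  geo <- export_structure(state)
  expect_identical(nrow(geo), 4L)
  expect_equal(geo$azimuth_deg, ((0:3) * 137.5) %% 360)
  # petiole tip sits at petiole length from the origin
  expect_equal(sqrt(geo$tip_x^2 + geo$tip_y^2 + geo$tip_z^2),
               state$phytomers$petiole_length)
  # empty plant gives an empty table
  empty <- state
  empty$phytomers <- empty$phytomers[0, ]
  expect_identical(nrow(export_structure(empty)), 0L)
})

test_that("declining petiole-blade ratio yields a conical arrangement", {
  for (tr in c("M", "L")) {
    state <- make_test_plant(tr, ranks = 1:4, lengths = 5)
    geo <- export_structure(state)
    # horizontal distance of the blade tip from the stem axis
    tip_r <- sqrt((geo$blade_cx + geo$semi_major_cm *
                     cos(geo$azimuth_deg * pi / 180))^2 +
                    (geo$blade_cy + geo$semi_major_cm *
                       sin(geo$azimuth_deg * pi / 180))^2)
    expect_true(all(diff(tip_r) < 0))
  }
})

test_that("OBJ export writes a mesh whose extent matches the organs", {
  state <- make_test_plant("M", ranks = 1L, lengths = 10)
  geo <- export_structure(state)
  path <- withr::local_tempfile(fileext = ".obj")
  write_obj(geo, path)
  txt <- readLines(path)
  verts <- do.call(rbind, lapply(strsplit(grep("^v ", txt, value = TRUE),
                                          " "), function(x) {
    as.numeric(x[2:4])
  }))
  # the farthest vertex is the distal blade edge:
  # petiole projection + blade length
  expected <- state$phytomers$petiole_length *
    cos(geo$elevation_deg * pi / 180) + 10
  expect_equal(max(sqrt(verts[, 1]^2 + verts[, 2]^2)), expected,
               tolerance = 1e-3)
  # empty structures still give a valid file
  empty <- geo[0, ]
  path2 <- withr::local_tempfile(fileext = ".obj")
  write_obj(empty, path2)
  expect_false(any(grepl("^v ", readLines(path2))))
})
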