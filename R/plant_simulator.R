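# The simulator proper: phyllochron-driven leaf initiation, per-rank blade
# extension, allometric geometry and whole-plant aggregation, advanced one
# day at a time.

#' Phenology parameters
#'
#' @param phyllochron Accumulated temperature between the appearance of
#'   successive leaves on the main stem, degC d (default 75).
#' @param initial_leaf_count Number of visible leaves at transfer into the
#'   chamber (default 1: plants were raised until one leaf was visible).
#' @return An object of class `phenology_params`.
#' @export
phenology_params <- function(phyllochron = 75, initial_leaf_count = 1L) {
  stopifnot(is.numeric(phyllochron), phyllochron > 0,
            initial_leaf_count >= 1)
  structure(list(phyllochron = phyllochron,
                 initial_leaf_count = as.integer(initial_leaf_count)),
            class = "phenology_params")
}

.empty_phytomers <- function() {
  tibble::tibble(rank = integer(), ts_init = numeric(), azimuth = numeric(),
                 blade_length = numeric(), blade_width = numeric(),
                 petiole_length = numeric(), blade_area = numeric(),
                 dry_mass = numeric())
}

#' Create a plant at transfer
#'
#' The initial leaves (rank 1 upward) are present at thermal time zero with
#' zero extension recorded; the first [step()] assigns their first measurable
#' lengths.
#'
#' @param treatment `"H"`, `"M"` or `"L"`.
#' @param phenology A [phenology_params()] object.
#' @return An object of class `plant_state`.
#' @export
new_plant <- function(treatment, phenology = phenology_params()) {
  .check_treatment(treatment)
  stopifnot(inherits(phenology, "phenology_params"))
  state <- structure(list(phytomers = .empty_phytomers(), ts = 0, day = 0L,
                          treatment = treatment,
                          totals = c(leaf_area = 0, leaf_dry_mass = 0)),
                     class = "plant_state")
  initiate_leaves(state, 0, phenology)
}

#' Initiate leaves up to a new thermal time
#'
#' One phytomer appears for every phyllochron multiple crossed in
#' `(state$ts, ts_new]`, so the leaf count always equals
#' `initial_leaf_count + floor(ts / phyllochron)`. Ranks are consecutive;
#' each new leaf is rotated 137.5 degrees from the previous one (spiral
#' phyllotaxis, a visualization convention). Initial leaves carry
#' `ts_init = 0`.
#'
#' @param state A `plant_state`.
#' @param ts_new Accumulated temperature to advance organogenesis to
#'   (>= `state$ts`).
#' @param phenology A [phenology_params()] object.
#' @return The updated `plant_state` (thermal time itself is not advanced;
#'   [step()] does that).
#' @export
initiate_leaves <- function(state, ts_new, phenology = phenology_params()) {
  stopifnot(inherits(state, "plant_state"),
            inherits(phenology, "phenology_params"))
  if (ts_new < state$ts) {
    stop("ts_new must not be smaller than the current thermal time",
         call. = FALSE)
  }
  target <- phenology$initial_leaf_count +
    floor(ts_new / phenology$phyllochron)
  n_cur <- nrow(state$phytomers)
  if (target > n_cur) {
    ranks <- seq.int(n_cur + 1L, target)
    ts_init <- pmax(0, (ranks - phenology$initial_leaf_count) *
                      phenology$phyllochron)
    new_rows <- tibble::tibble(
      rank = as.integer(ranks), ts_init = ts_init,
      azimuth = ((ranks - 1) * 137.5) %% 360,
      blade_length = 0, blade_width = 0, petiole_length = 0,
      blade_area = 0, dry_mass = 0)
    state$phytomers <- rbind(state$phytomers, new_rows)
  }
  state
}

# Raw (pre-monotone) blade length of one rank at plant thermal time ts.
# Ranks beyond the packaged table reuse the highest parameterized rank's
# curve, shifted by the difference in initiation thermal time.
.raw_blade_length <- function(rank, ts_init, ts, treatment, phenology) {
  if (ts <= 0) return(0)
  max_rank <- max_parameterized_rank(treatment)
  has_params <- rank <= max_rank &&
    !is.null(.store_lookup("leaf_extension", treatment, rank))
  if (has_params) {
    p <- leaf_extension_params(rank, treatment)
    eff_ts <- ts
  } else {
    p <- leaf_extension_params(max_rank, treatment)
    ref_init <- (max_rank - phenology$initial_leaf_count) *
      phenology$phyllochron
    eff_ts <- ts - (ts_init - max(0, ref_init))
  }
  if (eff_ts <= 0) return(0)
  leaf_length(eff_ts, p)
}

#' Update one phytomer to a new thermal time
#'
#' Blade length is the running maximum of the rank's extension curve
#' evaluated at plant thermal time, so it never shrinks even where the raw
#' fitted curve decays (the positive-slope low-temperature rows). Width,
#' petiole length, area and dry mass are recomputed from the updated length
#' through the allometric regressions.
#'
#' @param phytomer A one-row phytomer tibble (as stored in a `plant_state`).
#' @param ts Plant accumulated temperature, degC d.
#' @param treatment `"H"`, `"M"` or `"L"`.
#' @param phenology A [phenology_params()] object.
#' @param k Blade shape factor, see [blade_geometry()].
#' @return The updated one-row tibble.
#' @export
update_leaf <- function(phytomer, ts, treatment,
                        phenology = phenology_params(), k = 0.7) {
  raw <- .raw_blade_length(phytomer$rank, phytomer$ts_init, ts, treatment,
                           phenology)
  len <- max(phytomer$blade_length, raw)
  geo <- blade_geometry(len, phytomer$rank, treatment, k = k)
  phytomer$blade_length <- len
  phytomer$blade_width <- geo$width
  phytomer$petiole_length <- geo$petiole_length
  phytomer$blade_area <- geo$area
  phytomer$dry_mass <- leaf_dry_mass(geo$area, phytomer$rank, treatment)
  phytomer
}

.update_all_leaves <- function(state, phenology, k) {
  ph <- state$phytomers
  if (nrow(ph) > 0 && state$ts > 0) {
    for (i in seq_len(nrow(ph))) {
      ph[i, ] <- update_leaf(ph[i, ], state$ts, state$treatment, phenology,
                             k = k)
    }
  }
  state$phytomers <- ph
  state$totals <- c(leaf_area = sum(ph$blade_area),
                    leaf_dry_mass = sum(ph$dry_mass))
  state
}

#' Advance a plant by one day
#'
#' Thermal time is recomputed multiplicatively from the day counter
#' (`ts = day * daily_increment(regime)`), so trajectories carry no
#' accumulation drift and repeated runs are bit-identical. Leaves are then
#' initiated, every phytomer updated, and whole-plant totals recomputed.
#'
#' @param state A `plant_state`.
#' @param regime A [temperature_regime()]. If the regime carries a preset
#'   tag (see [regime_preset()]) it must match the plant's treatment.
#' @param phenology A [phenology_params()] object.
#' @param k Blade shape factor.
#' @return The advanced `plant_state`.
#' @export
step <- function(state, regime, phenology = phenology_params(), k = 0.7) {
  stopifnot(inherits(state, "plant_state"),
            inherits(regime, "temperature_regime"))
  preset <- attr(regime, "preset")
  if (!is.null(preset) && preset != state$treatment) {
    stop("config error: regime preset ", preset,
         " does not match plant treatment ", state$treatment, call. = FALSE)
  }
  state$day <- state$day + 1L
  state$ts <- state$day * daily_increment(regime)
  state <- initiate_leaves(state, state$ts, phenology)
  .update_all_leaves(state, phenology, k)
}

#' @export
print.plant_state <- function(x, ...) {
  cat("Plant (treatment ", x$treatment, "), day ", x$day, ", ts ",
      format(x$ts, digits = 6), " degC d\n", sep = "")
  cat("  leaves:", nrow(x$phytomers),
      " total blade area:", format(x$totals[["leaf_area"]], digits = 5),
      "cm2  total dry mass:",
      format(x$totals[["leaf_dry_mass"]], digits = 5), "mg\n")
  invisible(x)
}

#' Run a growth simulation
#'
#' Drives a plant through `n_days` under one treatment and returns daily
#' whole-plant and per-leaf trajectories. Geometric totals (sums of the
#' per-leaf allometric areas and masses) are always emitted; in
#' `mode = "empirical"` the whole-plant empirical curves are reported
#' alongside: leaf area from the four-parameter sigmoid and dry mass from
#' the plant-level double logistic (normalized unless `anchors` supply an
#' absolute endpoint mass). The two accountings are deliberately not forced
#' to agree; their ratio is a model diagnostic.
#'
#' With `carbon = TRUE` a mechanistic daily carbon budget is added: each
#' day's per-leaf absorbed light is estimated by Monte-Carlo ray casting in
#' the chamber scene and converted into a dry-mass increment (columns
#' `gross_umol`, `resp_maint_umol`, `resp_growth_umol`, `dmass_mg`).
#'
#' @param treatment `"H"`, `"M"` or `"L"`.
#' @param n_days Number of simulated days (>= 0).
#' @param mode `"geometric"` or `"empirical"`.
#' @param regime Temperature regime; defaults to the treatment's preset.
#' @param phenology A [phenology_params()] object.
#' @param k Blade shape factor.
#' @param anchors Optional [denorm_anchors()] for the empirical dry-mass
#'   curve. Default: `y_max = 1` (normalized output) and `ts_max` equal to
#'   the 30-day accumulated temperature of the regime, the duration of the
#'   underlying chamber series.
#' @param carbon If `TRUE`, add the mechanistic carbon-budget columns.
#' @param scene Chamber scene for the carbon mode (default
#'   [chamber_scene()]).
#' @param photo Photosynthesis parameters, see [photosynthesis_params()].
#' @param budget Carbon-budget coefficients, see [carbon_budget_params()].
#' @param n_rays Rays per day for the absorbed-light estimate.
#' @param seed Base seed for the carbon-mode Monte Carlo (day number is
#'   added so each day draws distinct rays).
#' @return A list of class `growth_trajectory` with tibbles `plant_daily`
#'   and `leaves_daily` and the final `plant_state` as `state`.
#' @export
#' @examples
#' traj <- run_simulation("M", 30)
#' tail(traj$plant_daily, 3)
run_simulation <- function(treatment, n_days,
                           mode = c("geometric", "empirical"),
                           regime = NULL,
                           phenology = phenology_params(), k = 0.7,
                           anchors = NULL, carbon = FALSE,
                           scene = NULL, photo = photosynthesis_params(),
                           budget = carbon_budget_params(),
                           n_rays = 20000, seed = 1L) {
  mode <- match.arg(mode)
  .check_treatment(treatment)
  if (n_days < 0) stop("n_days must be non-negative", call. = FALSE)
  if (is.null(regime)) regime <- regime_preset(treatment)
  if (is.null(anchors)) {
    anchors <- denorm_anchors(y_max = 1,
                              ts_max = 30 * daily_increment(regime))
  }
  if (carbon && is.null(scene)) scene <- chamber_scene()
  dm_params <- plant_dry_mass_params(treatment)
  la_params <- leaf_area_params(treatment)

  state <- new_plant(treatment, phenology)
  plant_rows <- vector("list", n_days + 1)
  leaf_rows <- vector("list", n_days + 1)
  carbon_mass <- 0

  snapshot <- function(state) {
    row <- tibble::tibble(
      day = state$day, ts = state$ts, n_leaves = nrow(state$phytomers),
      total_area_cm2 = state$totals[["leaf_area"]],
      total_mass_mg = state$totals[["leaf_dry_mass"]])
    if (mode == "empirical") {
      row$area_empirical_cm2 <- whole_plant_leaf_area(state$ts, la_params)
      row$mass_empirical <- dry_mass(state$ts, dm_params, anchors)
    }
    row
  }
  leaves_snapshot <- function(state) {
    ph <- state$phytomers
    tibble::tibble(day = state$day, rank = ph$rank,
                   length_cm = ph$blade_length, width_cm = ph$blade_width,
                   petiole_cm = ph$petiole_length, area_cm2 = ph$blade_area,
                   mass_mg = ph$dry_mass)
  }

  for (d in 0:n_days) {
    if (d > 0) {
      state <- step(state, regime, phenology, k = k)
    }
    row <- snapshot(state)
    if (carbon) {
      if (state$day == 0) {
        cb <- list(gross_umol = 0, resp_maint_umol = 0,
                   resp_growth_umol = 0, increment_mg = 0)
      } else {
        structure_tab <- export_structure(state)
        absorbed <- per_leaf_absorbed_par(scene, structure_tab,
                                          n_rays = n_rays,
                                          seed = seed + state$day)
        cb <- daily_carbon_budget(state, absorbed, regime, photo, budget)
      }
      carbon_mass <- carbon_mass + cb$increment_mg
      row$gross_umol <- cb$gross_umol
      row$resp_maint_umol <- cb$resp_maint_umol
      row$resp_growth_umol <- cb$resp_growth_umol
      row$dmass_mg <- cb$increment_mg
      row$mass_carbon_mg <- carbon_mass
    }
    plant_rows[[d + 1]] <- row
    leaf_rows[[d + 1]] <- leaves_snapshot(state)
  }
  structure(list(plant_daily = do.call(rbind, plant_rows),
                 leaves_daily = do.call(rbind, leaf_rows),
                 state = state, treatment = treatment, mode = mode),
            class = "growth_trajectory")
}

#' @export
print.growth_trajectory <- function(x, ...) {
  last <- x$plant_daily[nrow(x$plant_daily), ]
  cat("Growth trajectory, treatment ", x$treatment, ", ", x$mode,
      " mode, ", last$day, " days\n", sep = "")
  cat("  final: ", last$n_leaves, " leaves, ",
      format(last$total_area_cm2, digits = 5), " cm2, ",
      format(last$total_mass_mg, digits = 5), " mg (geometric)\n", sep = "")
  invisible(x)
}
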