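# Simplified C3 leaf photosynthesis (Farquhar-type minimum of the Rubisco-
# and electron-transport-limited rates) and a whole-plant daily carbon
# budget. Stomatal conductance and leaf energy balance are deliberately
# collapsed: intercellular CO2 is a fixed fraction of ambient and leaf
# temperature equals air temperature. All coefficients are config inputs.

#' Leaf photosynthesis parameters
#'
#' Defaults are generic literature values for a well-watered C3 rosette
#' leaf; they are configuration inputs, not fitted quantities. Temperature
#' responses are Q10-style around 25 degC.
#'
#' @param vcmax25 Maximum carboxylation rate at 25 degC, umol m-2 s-1.
#' @param jmax25 Maximum electron transport rate at 25 degC, umol m-2 s-1.
#' @param rd25 Dark respiration at 25 degC, umol m-2 s-1.
#' @param alpha_q Effective quantum yield of electron transport on an
#'   incident-light basis, mol e- per mol photon.
#' @param theta Curvature of the light response of electron transport.
#' @param kc25 Michaelis constant for CO2 at 25 degC, umol mol-1.
#' @param ko25 Michaelis constant for O2 at 25 degC, mmol mol-1.
#' @param gamma_star25 CO2 compensation point without dark respiration at
#'   25 degC, umol mol-1.
#' @param o2 Intercellular O2, mmol mol-1.
#' @param ca Ambient CO2, umol mol-1.
#' @param ci_ratio Fixed intercellular-to-ambient CO2 ratio.
#' @param q10_vcmax,q10_jmax,q10_rd,q10_kc,q10_ko,q10_gamma Q10 factors.
#' @param absorptance Leaf absorptance (used to convert absorbed flux maps
#'   back to an incident-light basis).
#' @return An object of class `photosynthesis_params`.
#' @export
photosynthesis_params <- function(vcmax25 = 60, jmax25 = 120, rd25 = 1.0,
                                  alpha_q = 0.3, theta = 0.7,
                                  kc25 = 404.9, ko25 = 278.4,
                                  gamma_star25 = 42.75, o2 = 210,
                                  ca = 400, ci_ratio = 0.7,
                                  q10_vcmax = 2.0, q10_jmax = 1.8,
                                  q10_rd = 2.0, q10_kc = 2.1,
                                  q10_ko = 1.2, q10_gamma = 1.75,
                                  absorptance = 0.85) {
  p <- as.list(environment())
  if (any(vapply(p, function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all photosynthesis parameters must be positive", call. = FALSE)
  }
  if (jmax25 <= vcmax25) {
    warning("jmax25 <= vcmax25 is unusual for C3 leaves", call. = FALSE)
  }
  structure(p, class = "photosynthesis_params")
}

.q10 <- function(x25, q10, t_leaf) x25 * q10^((t_leaf - 25) / 10)

#' Net CO2 assimilation of a C3 leaf
#'
#' `A = min(Wc, Wj) - Rd(T)`: the minimum of the Rubisco-limited rate
#' `Wc = Vcmax (Ci - G*) / (Ci + Kc (1 + O/Ko))` and the electron-transport-
#' limited rate `Wj = J (Ci - G*) / (4 Ci + 8 G*)`, where `J` is the smaller
#' root of the non-rectangular hyperbola
#' `theta J^2 - (alpha Q + Jmax) J + alpha Q Jmax = 0`. Continuous, piecewise
#' smooth, and monotone non-decreasing in light; in darkness it returns
#' `-Rd`. Leaf temperature is taken equal to air temperature.
#'
#' @param ppfd Incident photosynthetic photon flux density,
#'   umol m-2 s-1 (>= 0; vectorized).
#' @param t_leaf Leaf (= air) temperature, degC.
#' @param p A [photosynthesis_params()] object.
#' @return Net assimilation, umol CO2 m-2 s-1.
#' @export
#' @examples
#' net_assimilation(150, 25, photosynthesis_params())
net_assimilation <- function(ppfd, t_leaf, p = photosynthesis_params()) {
  if (any(ppfd < 0)) stop("ppfd must be non-negative", call. = FALSE)
  gross_assimilation(ppfd, t_leaf, p) - .q10(p$rd25, p$q10_rd, t_leaf)
}

#' Gross CO2 assimilation of a C3 leaf
#'
#' The `min(Wc, Wj)` part of [net_assimilation()], without dark
#' respiration. Used by the daily budget, where all respiratory losses are
#' booked separately.
#'
#' @inheritParams net_assimilation
#' @return Gross assimilation, umol CO2 m-2 s-1.
#' @export
gross_assimilation <- function(ppfd, t_leaf, p = photosynthesis_params()) {
  if (any(ppfd < 0)) stop("ppfd must be non-negative", call. = FALSE)
  vcmax <- .q10(p$vcmax25, p$q10_vcmax, t_leaf)
  jmax <- .q10(p$jmax25, p$q10_jmax, t_leaf)
  kc <- .q10(p$kc25, p$q10_kc, t_leaf)
  ko <- .q10(p$ko25, p$q10_ko, t_leaf)
  gs <- .q10(p$gamma_star25, p$q10_gamma, t_leaf)
  ci <- p$ci_ratio * p$ca
  i2 <- p$alpha_q * ppfd
  disc <- sqrt(pmax(0, (i2 + jmax)^2 - 4 * p$theta * i2 * jmax))
  j <- (i2 + jmax - disc) / (2 * p$theta)
  wc <- vcmax * (ci - gs) / (ci + kc * (1 + p$o2 / ko))
  wj <- j * (ci - gs) / (4 * ci + 8 * gs)
  pmax(0, pmin(wc, wj))
}

#' Whole-plant carbon-budget coefficients
#'
#' @param maint25 Maintenance respiration coefficient at 25 degC, mg CH2O
#'   per mg dry mass per day (covers all dark respiration).
#' @param q10_maint Q10 of maintenance respiration.
#' @param yg Growth conversion efficiency: fraction of the net assimilate
#'   pool incorporated into structure, the rest being growth respiration.
#' @param ch2o_per_dm Grams of CH2O required per gram of structural dry
#'   mass.
#' @return An object of class `carbon_budget_params`.
#' @export
carbon_budget_params <- function(maint25 = 0.015, q10_maint = 2.0,
                                 yg = 0.75, ch2o_per_dm = 1.0) {
  stopifnot(maint25 >= 0, q10_maint > 0, yg > 0, yg <= 1, ch2o_per_dm > 0)
  structure(list(maint25 = maint25, q10_maint = q10_maint, yg = yg,
                 ch2o_per_dm = ch2o_per_dm), class = "carbon_budget_params")
}

# mg CH2O per umol CO2 fixed (30 g mol-1 CH2O)
.MG_CH2O_PER_UMOL <- 30e-3

#' Daily whole-plant carbon budget
#'
#' Gross assimilation of each leaf at its Monte-Carlo absorbed light,
#' integrated over the photoperiod at the day temperature, minus maintenance
#' respiration (proportional to standing dry mass, Q10 response at the 24-h
#' mean temperature) and growth respiration (a `1 - yg` share of any
#' positive net pool). The residual pool converts to a dry-mass increment
#' through the CH2O-to-dry-mass coefficient, so the books balance exactly:
#' `gross = resp_maint + resp_growth + increment * ch2o_per_dm / 0.03`
#' (all fluxes in umol CO2 equivalents per day).
#'
#' In darkness the increment is strictly negative (maintenance only).
#'
#' @param plant A `plant_state` (supplies per-leaf areas and standing dry
#'   mass).
#' @param absorbed_par_map A tibble from [per_leaf_absorbed_par()] with
#'   `rank` and `absorbed_umol_s`.
#' @param regime A [temperature_regime()] (photoperiod and temperatures).
#' @param photo A [photosynthesis_params()] object.
#' @param budget A [carbon_budget_params()] object.
#' @return A list: `gross_umol`, `resp_maint_umol`, `resp_growth_umol`
#'   (umol CO2 d-1) and `increment_mg` (mg dry mass d-1).
#' @export
daily_carbon_budget <- function(plant, absorbed_par_map, regime,
                                photo = photosynthesis_params(),
                                budget = carbon_budget_params()) {
  stopifnot(inherits(plant, "plant_state"),
            inherits(regime, "temperature_regime"))
  ph <- plant$phytomers
  day_s <- regime$photoperiod_h * 3600
  gross_umol <- 0
  if (nrow(ph) > 0 && day_s > 0) {
    idx <- match(ph$rank, absorbed_par_map$rank)
    absorbed <- ifelse(is.na(idx), 0, absorbed_par_map$absorbed_umol_s[idx])
    area_m2 <- ph$blade_area / 1e4
    ppfd <- ifelse(area_m2 > 0,
                   absorbed / (area_m2 * photo$absorptance), 0)
    a_gross <- gross_assimilation(ppfd, regime$t_day, photo)
    gross_umol <- sum(a_gross * area_m2) * day_s
  }
  p_h <- regime$photoperiod_h
  t_mean <- (regime$t_night * (24 - p_h) + regime$t_day * p_h) / 24
  mass_mg <- plant$totals[["leaf_dry_mass"]]
  resp_maint_umol <- budget$maint25 * budget$q10_maint^((t_mean - 25) / 10) *
    mass_mg / .MG_CH2O_PER_UMOL
  net_pool <- gross_umol - resp_maint_umol
  if (net_pool > 0) {
    resp_growth_umol <- (1 - budget$yg) * net_pool
    growth_umol <- budget$yg * net_pool
  } else {
    resp_growth_umol <- 0
    growth_umol <- net_pool
  }
  increment_mg <- growth_umol * .MG_CH2O_PER_UMOL / budget$ch2o_per_dm
  list(gross_umol = gross_umol, resp_maint_umol = resp_maint_umol,
       resp_growth_umol = resp_growth_umol, increment_mg = increment_mg)
}
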