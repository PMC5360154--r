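# Rank-dependent leaf allometry: blade width, petiole length, blade area and
# dry mass are all derived from blade length through linear (WLR, PBR) and
# exponential (LMA) regressions on leaf rank.

.rank_guard <- function(rank, what) {
  if (any(rank < 0)) stop(what, ": rank must be non-negative", call. = FALSE)
  if (any(rank > 8)) {
    warning(what, ": rank beyond the measured range 1-8, ",
            "linear regression extrapolated", call. = FALSE)
  }
}

#' Blade width-to-length ratio at a given rank
#'
#' Linear in rank with treatment-specific coefficients; decreases with rank
#' in all three treatments (younger, higher-ranked leaves are relatively
#' narrower).
#'
#' @param rank Leaf rank (rank 0 returns the regression intercept).
#' @param treatment `"H"`, `"M"` or `"L"`.
#' @return Width/length ratio, dimensionless (vectorized over `rank`).
#' @export
#' @examples
#' wlr(1, "M")
wlr <- function(rank, treatment) {
  .rank_guard(rank, "wlr")
  cf <- allometry_set(treatment)$wlr
  cf[["intercept"]] + cf[["slope"]] * rank
}

#' Petiole-length to blade-length ratio at a given rank
#'
#' Linear in rank; the slope is positive at high temperature and negative at
#' medium and low temperature, where the shortening petioles of upper leaves
#' produce a conical leaf arrangement. Non-positive evaluations (possible
#' far beyond the measured ranks) are clamped to a small positive value with
#' a warning.
#'
#' @inheritParams wlr
#' @return Petiole/blade length ratio, dimensionless (vectorized).
#' @export
pbr <- function(rank, treatment) {
  .rank_guard(rank, "pbr")
  cf <- allometry_set(treatment)$pbr
  out <- cf[["intercept"]] + cf[["slope"]] * rank
  if (any(out <= 0)) {
    warning("pbr: non-positive ratio clamped to 0.001", call. = FALSE)
    out[out <= 0] <- 0.001
  }
  out
}

#' Leaf mass per area at a given rank
#'
#' Exponential in rank for the high and medium treatments
#' (`coeff * exp(exp_rate * rank)`); a constant treatment mean of
#' 0.01639 kg m-2 for the low treatment, where the rank relationship was not
#' significant.
#'
#' @inheritParams wlr
#' @return LMA, kg m-2 (vectorized).
#' @export
#' @examples
#' lma(1:5, "H")
lma <- function(rank, treatment) {
  .rank_guard(rank, "lma")
  m <- allometry_set(treatment)$lma
  if (m$type == "const") {
    rep(m$value, length(rank))
  } else {
    m$coeff * exp(m$exp * rank)
  }
}

#' Blade width, petiole length and blade area from blade length
#'
#' Composes the rank allometry: `width = length * WLR(rank)`,
#' `petiole = length * PBR(rank)`, `area = k * length * width` with a
#' dimensionless shape factor `k` describing how much of the enclosing
#' length-by-width rectangle the blade outline fills (default 0.7, a typical
#' elliptical dicot blade).
#'
#' @param length Blade length, cm (>= 0; vectorized).
#' @param rank Leaf rank (scalar).
#' @param treatment `"H"`, `"M"` or `"L"`.
#' @param k Blade shape factor, dimensionless.
#' @return A list with numeric elements `width` (cm), `petiole_length` (cm)
#'   and `area` (cm2).
#' @export
#' @examples
#' blade_geometry(10, 1, "M")
blade_geometry <- function(length, rank, treatment, k = 0.7) {
  if (any(length < 0)) stop("blade length must be non-negative", call. = FALSE)
  w <- length * wlr(rank, treatment)
  p <- length * pbr(rank, treatment)
  list(width = w, petiole_length = p, area = k * length * w)
}

#' Leaf dry mass from blade area via LMA
#'
#' `mass_mg = area_cm2 * LMA_kg_m2 * 100` (1 kg m-2 equals 100 mg cm-2... the
#' factor collapses 1 kg = 1e6 mg against 1 m2 = 1e4 cm2).
#'
#' @param area Blade area, cm2 (>= 0; vectorized).
#' @param rank Leaf rank (scalar).
#' @param treatment `"H"`, `"M"` or `"L"`.
#' @return Dry mass, mg.
#' @export
#' @examples
#' leaf_dry_mass(100, 1, "L")  # 100 cm2 at 0.01639 kg m-2 -> 163.9 mg
leaf_dry_mass <- function(area, rank, treatment) {
  if (any(area < 0)) stop("area must be non-negative", call. = FALSE)
  area * lma(rank, treatment) * 100
}
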