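# The four empirical growth-curve families: per-rank blade extension
# (logistic in accumulated temperature), normalized dry-mass (modified
# logistic with a quadratic exponent, single or piecewise double), and
# whole-plant leaf area (four-parameter sigmoid).

# exponent clip guard: keeps exp() finite on extreme fitted coefficients
.exp_clipped <- function(x) exp(pmin(pmax(x, -700), 700))

#' Blade length at a given accumulated temperature
#'
#' Evaluates `y_m / (1 + (ts / ts_0)^b)`. With the usual negative `b` this
#' rises sigmoidally from 0 toward the maximum blade length `y_m`, passing
#' exactly through `y_m / 2` at `ts = ts_0`. The low-temperature rows 1, 2
#' and 4 carry positive `b`, making the raw curve a decreasing step; this
#' evaluator stays faithful to that form, and the simulator enforces
#' monotone extension through a running maximum (see [run_simulation()]).
#'
#' @param ts Accumulated temperature since transfer, degC d; must be > 0
#'   (the power is undefined at 0 for negative `b`).
#' @param params A [leaf_extension_params()] object or a list with `y_m`,
#'   `ts_0`, `b`.
#' @return Blade length, cm (vectorized over `ts`).
#' @export
#' @examples
#' p <- leaf_extension_params(3, "H")
#' leaf_length(p$ts_0, p)  # exactly y_m / 2
leaf_length <- function(ts, params) {
  if (any(!is.finite(ts)) || any(ts <= 0)) {
    stop("ts must be positive and finite", call. = FALSE)
  }
  params$y_m / (1 + (ts / params$ts_0)^params$b)
}

#' Normalized dry mass from a modified logistic
#'
#' Evaluates `y_m / (1 + exp(a*t^2 + b*t + c))` on normalized time
#' `t = ts / ts_max` in `[0, 1]`. Values outside the calibrated range are
#' permitted but warned about. Exponent arguments are clipped at +-700
#' before exponentiation.
#'
#' @param ts_norm Normalized accumulated temperature (dimensionless).
#' @param params A `single_logistic_params` object or list with `y_m`, `a`,
#'   `b`, `c`.
#' @return Normalized dry mass (dimensionless, vectorized).
#' @export
normalized_dry_mass <- function(ts_norm, params) {
  if (any(ts_norm < 0 | ts_norm > 1)) {
    warning("ts_norm outside [0, 1]: evaluating beyond the calibrated range",
            call. = FALSE)
  }
  arg <- params$a * ts_norm^2 + params$b * ts_norm + params$c
  params$y_m / (1 + .exp_clipped(arg))
}

#' Normalized dry mass from a piecewise double logistic
#'
#' The lower branch applies strictly below the transition point `ts_tr`, the
#' upper branch at and above it, exactly as fitted: no smoothing or
#' continuity constraint is imposed. Use [branch_discontinuity()] to measure
#' the jump at the transition.
#'
#' @param ts_norm Normalized accumulated temperature.
#' @param params A `double_logistic_params` object (see
#'   [plant_dry_mass_params()]).
#' @return Normalized dry mass (vectorized).
#' @export
double_logistic_dry_mass <- function(ts_norm, params) {
  stopifnot(inherits(params, "double_logistic_params"))
  lower <- normalized_dry_mass(ts_norm, params$lower)
  upper <- normalized_dry_mass(ts_norm, params$upper)
  ifelse(ts_norm < params$ts_tr, lower, upper)
}

#' Jump magnitude of a double logistic at its transition point
#'
#' Both branches are continuous functions, so the left-hand limit of the
#' lower branch equals its value at `ts_tr`; the jump is the absolute
#' difference between the two branch values there. It is reported as a
#' diagnostic, never hidden or smoothed away.
#'
#' @param params A `double_logistic_params` object.
#' @return Absolute jump, dimensionless.
#' @export
#' @examples
#' branch_discontinuity(plant_dry_mass_params("H"))
branch_discontinuity <- function(params) {
  stopifnot(inherits(params, "double_logistic_params"))
  abs(normalized_dry_mass(params$ts_tr, params$lower) -
        normalized_dry_mass(params$ts_tr, params$upper))
}

#' Denormalization anchors for the dry-mass curves
#'
#' The dry-mass curves are fitted on series normalized by their final value
#' and final accumulated temperature; these anchors invert that scaling.
#' They are run inputs, not packaged constants: the published treatment-mean
#' dry weights are means across sampling dates, not endpoint values, so no
#' absolute default is shipped.
#'
#' @param y_max Absolute dry mass at the series end, mg (> 0).
#' @param ts_max Accumulated temperature at the series end, degC d (> 0).
#' @return An object of class `denorm_anchors`.
#' @export
denorm_anchors <- function(y_max, ts_max) {
  if (!is.numeric(y_max) || !is.numeric(ts_max) || y_max <= 0 || ts_max <= 0) {
    stop("anchors y_max and ts_max must both be positive", call. = FALSE)
  }
  structure(list(y_max = y_max, ts_max = ts_max), class = "denorm_anchors")
}

#' Absolute dry mass at a given accumulated temperature
#'
#' Evaluates the normalized curve at `ts / ts_max` and rescales by `y_max`.
#' Dispatches on the curve class: single logistics and piecewise double
#' logistics are both accepted.
#'
#' @param ts Accumulated temperature, degC d.
#' @param params A `single_logistic_params` or `double_logistic_params`
#'   object.
#' @param anchors A [denorm_anchors()] object. `denorm_anchors(1, 1)` reduces
#'   to the normalized curve.
#' @return Dry mass in the units of `y_max` (vectorized).
#' @export
dry_mass <- function(ts, params, anchors) {
  stopifnot(inherits(anchors, "denorm_anchors"))
  t_norm <- ts / anchors$ts_max
  y <- if (inherits(params, "double_logistic_params")) {
    double_logistic_dry_mass(t_norm, params)
  } else {
    normalized_dry_mass(t_norm, params)
  }
  anchors$y_max * y
}

#' Whole-plant leaf area at a given accumulated temperature
#'
#' Evaluates `la_0 + la_max / (1 + exp(-b * (ts - ts_m)))`: a sigmoid rising
#' from near `la_0` through the exact midpoint `la_0 + la_max / 2` at
#' `ts = ts_m` toward the plateau `la_0 + la_max`, matching the described
#' exponential, linear and maturation phases. This exponential-argument form
#' is an interpretation of the curve as originally printed; see
#' [whole_plant_leaf_area_printed()] for the raw power form and the methods
#' vignette for the rationale.
#'
#' @param ts Accumulated temperature, degC d (>= 0).
#' @param params A [leaf_area_params()] object or list with `la_0`, `la_max`,
#'   `ts_m`, `b`.
#' @return Leaf area, cm2 (vectorized).
#' @export
#' @examples
#' whole_plant_leaf_area(380, leaf_area_params("H"))  # midpoint: 76.5 cm2
whole_plant_leaf_area <- function(ts, params) {
  if (any(ts < 0)) stop("ts must be non-negative", call. = FALSE)
  params$la_0 + params$la_max /
    (1 + .exp_clipped(-params$b * (ts - params$ts_m)))
}

#' Whole-plant leaf area, raw printed power form
#'
#' Evaluates `la_0 + la_max / (1 + (ts - ts_m)^(-b))` literally. For
#' `ts <= ts_m` the negative base with a non-integer exponent is undefined
#' and `NaN` is returned. Provided for comparison only; the simulator uses
#' [whole_plant_leaf_area()].
#'
#' @inheritParams whole_plant_leaf_area
#' @return Leaf area, cm2, `NaN` where the form is undefined.
#' @export
whole_plant_leaf_area_printed <- function(ts, params) {
  base <- ts - params$ts_m
  out <- rep(NaN, length(ts))
  ok <- base > 0
  out[ok] <- params$la_0 + params$la_max / (1 + base[ok]^(-params$b))
  out
}
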