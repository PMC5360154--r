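# Thermal time: converts a square-wave day/night temperature regime into
# daily increments of accumulated temperature above a base of 5 degC.

#' Define a day/night temperature regime
#'
#' A regime is a square wave: the day temperature applies during the
#' photoperiod, the night temperature during the remaining `24 - photoperiod_h`
#' hours. Growth accumulates thermal time only above the base temperature.
#'
#' @param t_night Night temperature, degC.
#' @param t_day Day temperature, degC.
#' @param photoperiod_h Hours of day temperature per 24 h (default 14).
#' @param t_base Base temperature for growth, degC (default 5).
#' @return An object of class `temperature_regime`.
#' @export
#' @examples
#' temperature_regime(18, 22)          # the medium chamber regime
#' daily_increment(temperature_regime(18, 22))
temperature_regime <- function(t_night, t_day, photoperiod_h = 14,
                               t_base = 5) {
  stopifnot(is.numeric(t_night), is.numeric(t_day),
            is.numeric(photoperiod_h), is.numeric(t_base))
  if (photoperiod_h < 0 || photoperiod_h > 24) {
    stop("invalid regime: photoperiod_h must lie within [0, 24]",
         call. = FALSE)
  }
  structure(list(t_night = t_night, t_day = t_day,
                 photoperiod_h = photoperiod_h, t_base = t_base),
            class = "temperature_regime")
}

#' Named chamber regime presets
#'
#' `"H"` is 26/30 degC night/day, `"M"` 18/22 degC, `"L"` 10/14 degC, all with
#' a 14-h photoperiod and a 5 degC base. These are the three growth-chamber
#' treatments the packaged parameter tables were derived under.
#'
#' @param name `"H"`, `"M"` or `"L"`.
#' @return A `temperature_regime` tagged with its preset name.
#' @export
regime_preset <- function(name) {
  name <- match.arg(name, c("H", "M", "L"))
  temps <- list(H = c(26, 30), M = c(18, 22), L = c(10, 14))[[name]]
  r <- temperature_regime(temps[1], temps[2])
  attr(r, "preset") <- name
  r
}

#' Daily thermal-time increment of a regime
#'
#' The 24-h mean temperature of the square wave minus the base temperature,
#' clamped at zero. Returned unrounded; the integer values quoted for the
#' chamber presets (23, 15, 7 degC d per day) are a reporting convention, see
#' [increment_label()].
#'
#' @param regime A [temperature_regime()].
#' @return Thermal-time increment, degC d per day (>= 0).
#' @export
daily_increment <- function(regime) {
  stopifnot(inherits(regime, "temperature_regime"))
  p <- regime$photoperiod_h
  mean_t <- (regime$t_night * (24 - p) + regime$t_day * p) / 24
  max(0, mean_t - regime$t_base)
}

#' Round an increment to its conventional integer label
#'
#' Round-half-up to the nearest integer, the convention under which the three
#' chamber presets print as 23, 15 and 7 degC d per day. Internal arithmetic
#' always uses the unrounded increment.
#'
#' @param x Numeric increment(s).
#' @return Integer vector.
#' @export
increment_label <- function(x) {
  as.integer(floor(x + 0.5))
}

#' Accumulated-temperature series over whole days
#'
#' Thermal time is zero at transfer into the chamber and advances by a
#' constant daily step, so `ts[k] = k * daily_increment(regime)` exactly.
#'
#' @param regime A [temperature_regime()].
#' @param n_days Number of days (>= 0).
#' @return A tibble with columns `day` (0..n_days) and `ts` (degC d).
#' @export
#' @examples
#' accumulate_thermal_time(regime_preset("M"), 30)
accumulate_thermal_time <- function(regime, n_days) {
  stopifnot(inherits(regime, "temperature_regime"))
  if (!is.numeric(n_days) || length(n_days) != 1 || n_days < 0 ||
      n_days != floor(n_days)) {
    stop("n_days must be a single non-negative integer", call. = FALSE)
  }
  day <- 0:n_days
  tibble::tibble(day = day, ts = day * daily_increment(regime))
}

#' @export
print.temperature_regime <- function(x, ...) {
  preset <- attr(x, "preset")
  cat("Temperature regime", if (!is.null(preset)) paste0("(preset ", preset, ")"),
      "\n  night/day:", x$t_night, "/", x$t_day, "degC,",
      x$photoperiod_h, "h photoperiod, base", x$t_base, "degC\n",
      " daily increment:", format(daily_increment(x), digits = 6),
      "degC d/day\n")
  invisible(x)
}
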