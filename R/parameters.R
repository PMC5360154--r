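# Packaged parameter store: all growth-curve and allometric coefficients used
# by the simulator, shipped as a plain-text CSV so they can be inspected,
# round-tripped and replaced wholesale.

.param_env <- new.env(parent = emptyenv())

#' Load the packaged parameter store
#'
#' Reads the CSV shipped under `extdata/growth_parameters.csv` (or a
#' user-supplied file in the same dialect) into a tibble with columns
#' `table_id`, `treatment`, `rank`, `parameter`, `value`. `rank` is `NA` for
#' plant-level entries. The store covers five families: per-rank blade
#' extension logistics, plant-level normalized dry-mass double logistics,
#' per-rank normalized dry-mass logistics, whole-plant leaf-area sigmoids,
#' and the width-length / petiole-blade / leaf-mass-per-area regressions.
#'
#' @param path Path to a parameter CSV; defaults to the packaged store.
#' @return A tibble, one row per coefficient.
#' @export
#' @examples
#' ps <- param_store()
#' subset(ps, table_id == "leaf_area" & treatment == "H")
param_store <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.param_env$store)) return(.param_env$store)
    path <- system.file("extdata", "growth_parameters.csv",
                        package = "napusgrow", mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        colClasses = c(table_id = "character",
                                       treatment = "character",
                                       rank = "integer",
                                       parameter = "character",
                                       value = "numeric"))
  required <- c("table_id", "treatment", "rank", "parameter", "value")
  if (!identical(names(df), required)) {
    stop("parameter store must have columns ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  .validate_store(df)
  out <- tibble::as_tibble(df)
  if (cache) .param_env$store <- out
  out
}

.validate_store <- function(df) {
  need <- list(
    leaf_extension = c("ts_0", "b", "y_m"),
    dry_mass_plant = c("y_m1", "a_1", "b_1", "c_1", "ts_tr",
                       "y_mh", "a_h", "b_h", "c_h"),
    leaf_area      = c("la_0", "ts_m", "la_max", "b"),
    wlr            = c("slope", "intercept"),
    pbr            = c("slope", "intercept")
  )
  for (tid in names(need)) {
    for (tr in c("H", "M", "L")) {
      if (tid == "leaf_extension") next  # per-rank, checked on access
      sub <- df[df$table_id == tid & df$treatment == tr, ]
      missing <- setdiff(need[[tid]], sub$parameter)
      if (length(missing)) {
        stop("parameter store incomplete: ", tid, "/", tr, " lacks ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
    }
  }
  if (anyDuplicated(df[c("table_id", "treatment", "rank", "parameter")])) {
    stop("parameter store contains duplicated entries", call. = FALSE)
  }
  invisible(df)
}

#' Serialize a parameter store back to CSV
#'
#' Writes the store in the same dialect it is read from, so that a
#' load/serialize cycle reproduces the packaged tables cell for cell.
#'
#' @param store A tibble as returned by [param_store()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_store <- function(store, path) {
  utils::write.csv(as.data.frame(store), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

.store_lookup <- function(table_id, treatment, rank = NULL, store = NULL) {
  store <- if (is.null(store)) param_store() else store
  sub <- store[store$table_id == table_id & store$treatment == treatment, ]
  if (is.null(rank)) sub <- sub[is.na(sub$rank), ]
  else sub <- sub[!is.na(sub$rank) & sub$rank == rank, ]
  if (nrow(sub) == 0) return(NULL)
  stats::setNames(sub$value, sub$parameter)
}

.check_treatment <- function(treatment) {
  if (!is.character(treatment) || length(treatment) != 1 ||
      !treatment %in% c("H", "M", "L")) {
    stop("treatment must be one of \"H\", \"M\", \"L\"", call. = FALSE)
  }
  treatment
}

#' Blade-extension logistic parameters for one rank and treatment
#'
#' Returns the packaged (y_m, ts_0, b) triple describing blade length as a
#' logistic in accumulated temperature. Ranks without a packaged entry (rank 5
#' at low temperature, and all ranks beyond 5) raise a missing-parameter
#' error; the simulator applies its own documented fallback instead.
#'
#' @param rank Leaf rank on the main stem (1 = oldest true leaf).
#' @param treatment `"H"`, `"M"` or `"L"`.
#' @param store Optional store tibble (defaults to the packaged one).
#' @return An object of class `leaf_extension_params`: a list with `y_m`
#'   (cm), `ts_0` (degC d), `b` (dimensionless), `rank` and `treatment`.
#' @export
#' @examples
#' leaf_extension_params(3, "H")
leaf_extension_params <- function(rank, treatment, store = NULL) {
  .check_treatment(treatment)
  v <- .store_lookup("leaf_extension", treatment, rank, store)
  if (is.null(v)) {
    stop("no blade-extension parameters packaged for rank ", rank,
         " at treatment ", treatment, call. = FALSE)
  }
  structure(list(y_m = v[["y_m"]], ts_0 = v[["ts_0"]], b = v[["b"]],
                 rank = as.integer(rank), treatment = treatment),
            class = "leaf_extension_params")
}

#' All packaged blade-extension parameter rows
#'
#' @param store Optional store tibble.
#' @return A tibble with columns `treatment`, `rank`, `y_m`, `ts_0`, `b`.
#' @export
leaf_extension_table <- function(store = NULL) {
  store <- if (is.null(store)) param_store() else store
  sub <- store[store$table_id == "leaf_extension", ]
  ranks <- sort(unique(sub$rank))
  rows <- list()
  for (tr in c("H", "M", "L")) {
    for (r in ranks) {
      v <- .store_lookup("leaf_extension", tr, r, store)
      if (is.null(v)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        treatment = tr, rank = as.integer(r),
        y_m = v[["y_m"]], ts_0 = v[["ts_0"]], b = v[["b"]])
    }
  }
  do.call(rbind, rows)
}

.single_logistic <- function(y_m, a, b, c) {
  structure(list(y_m = y_m, a = a, b = b, c = c),
            class = "single_logistic_params")
}

.double_logistic <- function(lower, upper, ts_tr) {
  stopifnot(ts_tr > 0, ts_tr < 1)
  structure(list(lower = lower, upper = upper, ts_tr = ts_tr),
            class = "double_logistic_params")
}

#' Plant-level normalized dry-mass curve parameters
#'
#' The whole-plant dry-matter series, normalized by its final mass and final
#' accumulated temperature, follows a piecewise (double) logistic with a
#' treatment-specific transition point on the normalized time axis.
#'
#' @inheritParams leaf_extension_params
#' @return A `double_logistic_params` object with elements `lower` and
#'   `upper` (each `single_logistic_params`: y_m, a, b, c) and `ts_tr`.
#' @export
#' @examples
#' plant_dry_mass_params("M")$ts_tr
plant_dry_mass_params <- function(treatment, store = NULL) {
  .check_treatment(treatment)
  v <- .store_lookup("dry_mass_plant", treatment, NULL, store)
  .double_logistic(
    lower = .single_logistic(v[["y_m1"]], v[["a_1"]], v[["b_1"]], v[["c_1"]]),
    upper = .single_logistic(v[["y_mh"]], v[["a_h"]], v[["b_h"]], v[["c_h"]]),
    ts_tr = v[["ts_tr"]])
}

#' Per-rank normalized dry-mass curve parameters
#'
#' Most rank/treatment combinations use a single modified logistic; rank 3 at
#' high temperature carries an additional upper branch and transition point
#' and is returned as a `double_logistic_params` object.
#'
#' @inheritParams leaf_extension_params
#' @return A `single_logistic_params` or `double_logistic_params` object.
#' @export
rank_dry_mass_params <- function(rank, treatment, store = NULL) {
  .check_treatment(treatment)
  v <- .store_lookup("dry_mass_rank", treatment, rank, store)
  if (is.null(v)) {
    stop("no dry-mass parameters packaged for rank ", rank,
         " at treatment ", treatment, call. = FALSE)
  }
  lower <- .single_logistic(v[["y_m"]], v[["a"]], v[["b"]], v[["c"]])
  if ("ts_tr" %in% names(v)) {
    .double_logistic(
      lower = lower,
      upper = .single_logistic(v[["y_mh"]], v[["a_h"]], v[["b_h"]],
                               v[["c_h"]]),
      ts_tr = v[["ts_tr"]])
  } else {
    lower
  }
}

#' Whole-plant leaf-area curve parameters
#'
#' @inheritParams leaf_extension_params
#' @return A `leaf_area_params` object: `la_0` and `la_max` (cm2), `ts_m`
#'   (degC d at maximal expansion rate) and `b` (per degC d).
#' @export
leaf_area_params <- function(treatment, store = NULL) {
  .check_treatment(treatment)
  v <- .store_lookup("leaf_area", treatment, NULL, store)
  structure(list(la_0 = v[["la_0"]], la_max = v[["la_max"]],
                 ts_m = v[["ts_m"]], b = v[["b"]], treatment = treatment),
            class = "leaf_area_params")
}

#' Allometric coefficient set for one treatment
#'
#' Bundles the width-length ratio (WLR) and petiole-blade ratio (PBR) linear
#' regressions on rank and the leaf-mass-per-area (LMA) model: exponential in
#' rank for the high and medium treatments, a constant for the low treatment
#' where the rank effect was not significant.
#'
#' @inheritParams leaf_extension_params
#' @return A list with elements `wlr`, `pbr` (each `c(slope, intercept)`) and
#'   `lma` (either `list(type = "exp", coeff, exp)` or
#'   `list(type = "const", value)`, kg m-2).
#' @export
allometry_set <- function(treatment, store = NULL) {
  .check_treatment(treatment)
  w <- .store_lookup("wlr", treatment, NULL, store)
  p <- .store_lookup("pbr", treatment, NULL, store)
  l <- .store_lookup("lma", treatment, NULL, store)
  lma <- if ("const" %in% names(l)) {
    list(type = "const", value = l[["const"]])
  } else {
    list(type = "exp", coeff = l[["coeff"]], exp = l[["exp"]])
  }
  list(treatment = treatment,
       wlr = c(slope = w[["slope"]], intercept = w[["intercept"]]),
       pbr = c(slope = p[["slope"]], intercept = p[["intercept"]]),
       lma = lma)
}

#' Highest leaf rank with packaged extension parameters
#'
#' @inheritParams leaf_extension_params
#' @return An integer (5 for H and M, 4 for L with the packaged store).
#' @export
max_parameterized_rank <- function(treatment, store = NULL) {
  store <- if (is.null(store)) param_store() else store
  sub <- store[store$table_id == "leaf_extension" &
                 store$treatment == treatment, ]
  as.integer(max(sub$rank))
}
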