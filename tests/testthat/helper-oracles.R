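# Shared helpers: relative error, and independent closed-form evaluators of
# the curve families used as oracles against the package implementations.

rel_err <- function(est, tru) {
  abs(unlist(est) - unlist(tru)) / pmax(abs(unlist(tru)), 1e-12)
}

# independent evaluators (deliberately written out, not calling the package)
oracle_leaf <- function(ts, y_m, ts_0, b) y_m / (1 + (ts / ts_0)^b)
oracle_logistic <- function(t, y_m, a, b, c) {
  y_m / (1 + exp(a * t^2 + b * t + c))
}
oracle_leaf_area <- function(ts, la_0, la_max, ts_m, b) {
  la_0 + la_max / (1 + exp(-b * (ts - ts_m)))
}

# every treatment/rank combination holding dry-mass curve parameters
rank_dry_mass_combos <- function() {
  out <- list()
  for (tr in c("H", "M", "L")) {
    for (r in 1:6) {
      p <- tryCatch(rank_dry_mass_params(r, tr), error = function(e) NULL)
      if (!is.null(p)) out[[length(out) + 1L]] <- list(treatment = tr,
                                                       rank = r, params = p)
    }
  }
  out
}

# a small hand-built plant state for geometry / budget tests
make_test_plant <- function(treatment = "M", ranks = 1:3, lengths = 5) {
  state <- new_plant(treatment)
  lengths <- rep_len(lengths, length(ranks))
  ph <- do.call(rbind, lapply(seq_along(ranks), function(i) {
    g <- blade_geometry(lengths[i], ranks[i], treatment)
    tibble::tibble(rank = as.integer(ranks[i]),
                   ts_init = 0, azimuth = ((ranks[i] - 1) * 137.5) %% 360,
                   blade_length = lengths[i], blade_width = g$width,
                   petiole_length = g$petiole_length, blade_area = g$area,
                   dry_mass = leaf_dry_mass(g$area, ranks[i], treatment))
  }))
  state$phytomers <- ph
  state$ts <- 100
  state$day <- 10L
  state$totals <- c(leaf_area = sum(ph$blade_area),
                    leaf_dry_mass = sum(ph$dry_mass))
  state
}
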