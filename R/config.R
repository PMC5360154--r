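# YAML run configuration: a thin layer mapping config keys onto the
# constructors, used by the command-line interface shipped under inst/cli.

#' Read a simulation run configuration
#'
#' Recognized top-level keys (all optional): `treatment` (`H`/`M`/`L`),
#' `regime` (either `preset: H|M|L` or explicit `t_night`, `t_day`,
#' `photoperiod_h`, `t_base`), `days`, `mode`, `phyllochron`,
#' `initial_leaf_count`, `shape_factor`, `anchors` (`y_max`, `ts_max`),
#' `carbon` (logical), `rays`, `seed`, and `scene` (passed to
#' [chamber_scene()]).
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return A list with `treatment`, `regime`, `n_days`, `mode`, `phenology`,
#'   `k`, `anchors`, `carbon`, `n_rays`, `seed` and `scene`, ready to splice
#'   into [run_simulation()].
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  treatment <- cfg$treatment %||% "M"
  regime <- if (is.null(cfg$regime)) {
    regime_preset(treatment)
  } else if (!is.null(cfg$regime$preset)) {
    regime_preset(cfg$regime$preset)
  } else {
    temperature_regime(cfg$regime$t_night, cfg$regime$t_day,
                       cfg$regime$photoperiod_h %||% 14,
                       cfg$regime$t_base %||% 5)
  }
  anchors <- if (is.null(cfg$anchors)) NULL else {
    denorm_anchors(cfg$anchors$y_max, cfg$anchors$ts_max)
  }
  scene <- if (is.null(cfg$scene)) NULL else do.call(chamber_scene, cfg$scene)
  list(treatment = treatment,
       regime = regime,
       n_days = cfg$days %||% 30,
       mode = cfg$mode %||% "geometric",
       phenology = phenology_params(cfg$phyllochron %||% 75,
                                    cfg$initial_leaf_count %||% 1L),
       k = cfg$shape_factor %||% 0.7,
       anchors = anchors,
       carbon = isTRUE(cfg$carbon),
       n_rays = cfg$rays %||% 20000,
       seed = cfg$seed %||% 1L,
       scene = scene)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
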