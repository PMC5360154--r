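Package: napusgrow
Title: Functional-Structural Growth Simulation of Young Winter Oilseed Rape
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates early vegetative growth of winter oilseed rape
    (Brassica napus L.) seedlings under contrasting day/night temperature
    regimes. Thermal time drives phyllochron-based leaf initiation; per-rank
    blade extension follows logistic kinetics; blade width, petiole length,
    area and dry mass derive from rank-dependent allometric regressions
    (width-length ratio, petiole-blade ratio, leaf mass per area). Whole-plant
    dry matter and leaf area follow empirical single, double-logistic and
    four-parameter sigmoid curves, and a curve-fitting module recovers all
    parameter families from longitudinal organ measurements. An optional
    mechanistic mode adds a Monte-Carlo growth-chamber light model and a
    Farquhar-type C3 leaf carbon budget.
License: MIT
Encoding: UTF-8
Imports:
    minpack.lm,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
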