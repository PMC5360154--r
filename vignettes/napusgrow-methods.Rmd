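---
title: "Modelling young oilseed rape growth with napusgrow: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling young oilseed rape growth with napusgrow: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napusgrow)
```

## The model

`napusgrow` simulates the first month of vegetative growth of winter oilseed
rape (*Brassica napus* L.) seedlings in growth chambers at three day/night
temperature regimes: high (26/30 °C), medium (18/22 °C) and low (10/14 °C),
each with a 14-h photoperiod. The model is a small functional–structural
plant model: an explicit list of phytomers (leaf + petiole) whose initiation,
extension and geometry are all driven by accumulated temperature, with
whole-plant empirical curves and an optional mechanistic light/carbon mode
layered on top.

Everything is a function of *thermal time*. A regime contributes
`max(0, mean24h(T) − 5)` °C d per day, where the 24-h mean weights the day
temperature by the photoperiod. The three presets give 23.33, 15.33 and
7.33 °C d d⁻¹; the conventional integer labels 23/15/7 are a round-half-up
reporting convention (`increment_label()`), while all internal arithmetic is
unrounded — over 30 days the high regime accumulates 700 °C d, which is what
the extension curves expect, not 690.

```{r increments}
sapply(c("H", "M", "L"), function(tr) daily_increment(regime_preset(tr)))
```

### Organogenesis

A new leaf appears on the main stem every 75 °C d (the phyllochron); plants
enter the chamber with one visible leaf. Leaf count is therefore exactly
`1 + floor(ts / 75)`. To keep this identity exact, the simulator recomputes
thermal time multiplicatively from the day counter at every step instead of
accumulating increments, so there is no floating-point drift and repeated
runs are bit-identical. Azimuths follow a 137.5° spiral and petiole
elevations decline 2° per rank from 60°; both are visualization conventions
with no physiological content and are exposed as arguments of
`export_structure()`.

### Blade extension

Each rank and treatment has a logistic blade-length curve
`y(ts) = y_m / (1 + (ts/ts_0)^b)` on *plant-level* accumulated temperature
(not per-leaf age): the fitted `ts_0` values already encode each rank's
delay. The low-temperature ranks 1, 2 and 4 carry *positive* slopes, making
the raw curve a decreasing step — an artefact of fitting leaves that were
already largely expanded. The raw evaluator `leaf_length()` stays faithful
to the fitted form; the simulator consumes it through a running maximum so
that a blade never shrinks. Ranks beyond the fitted table (the high regime
initiates ten leaves in a month but only five ranks were measured) reuse the
highest fitted rank's curve time-shifted by the difference in initiation
thermal time; this fallback is a simulator necessity, clearly a modelling
extrapolation, and the affected ranks are visible in `leaves_daily`.

Two numerical cautions documented here because tests rely on them: the curve
passes *exactly* through `y_m/2` at `ts = ts_0` (the power is exactly 1),
and the approach to the asymptote is slow when `|b|` is small — for
`|b| < ~0.5` the curve is still far from `y_m` even at 10⁶ °C d, so the
shallow rank-1/2 curves should not be read as saturating sigmoids at all.

### Allometry

Blade width, petiole length, area and dry mass all derive from blade length
and rank: `width = WLR(r)·length`, `petiole = PBR(r)·length`,
`area = k·length·width`, `mass = area·LMA(r)·100` (mg from cm² and
kg m⁻²). WLR and PBR are linear in rank per treatment; LMA is exponential in
rank for the high and medium treatments and the constant treatment mean
0.01639 kg m⁻² at low temperature, where the rank effect was not
significant. The blade shape factor `k = 0.7` (fraction of the enclosing
rectangle filled by the outline, a typical elliptic dicot blade) is our
choice — the source regressions never state a blade outline — and is
config-exposed. The high-temperature WLR intercept was originally reported
as 0.08921; we transcribe 0.8921, since the reported value is inconsistent
with its own slope, with the other intercepts and with the mean
high-temperature WLR of 0.849 (the original value is kept as a comment in
the parameter CSV). Beyond rank 8 the linear regressions are
extrapolations: the evaluators warn but do not fail, and PBR is clamped to a
small positive value if the steep low-temperature slope crosses zero.

### Whole-plant empirical curves

Plant-level dry mass was fitted on doubly normalized series (mass by final
mass, thermal time by final thermal time) with a modified logistic
`y' = y_m / (1 + exp(a t² + b t + c))`, piecewise with separate lower/upper
branches joined at a transition point `ts_tr` for the whole plant (and for
rank 3 at high temperature). Three consequences we preserve rather than
repair:

* the branches need not meet: `branch_discontinuity()` reports the jump
  (0.014 for H, 0.091 for M plant-level) instead of smoothing it;
* the printed upper-branch form has amplitude 1, but the rank-level table
  carries an upper amplitude of 15.31 for one leaf, so both the evaluator
  and the fitter treat the upper amplitude as a free parameter;
* the fitted quadratic exponents have interior vertices, so the curve can
  *dip* slightly (e.g. the medium upper branch decreases until
  `t' ≈ 0.83` before rising); the empirical mass column of a trajectory is
  therefore faithful to the curve, not forced monotone. Geometric totals,
  by contrast, are monotone by construction.

Denormalization anchors (`y_max`, `ts_max`) are run inputs, not packaged
constants: the published treatment-mean dry weights are means across
sampling dates, unsuitable as endpoint anchors. Defaults are `y_max = 1`
(output stays normalized) and `ts_max` equal to the 30-day accumulated
temperature of the regime, the duration of the underlying experiment.

Whole-plant leaf area uses
`LA(ts) = LA_0 + LA_max / (1 + exp(−b(ts − TS_m)))`. The curve as
originally typeset is a power form `(ts − TS_m)^(−b)`, which is undefined
for `ts ≤ TS_m` and cannot produce a sigmoid with `b ≈ 0.02` per °C d; the
exponential-argument logistic matches the described exponential/linear/
maturation phases, makes `b`'s units sensible, and passes exactly through
the midpoint `LA_0 + LA_max/2` at `TS_m`. The literal printed form remains
available as `whole_plant_leaf_area_printed()` for comparison.

```{r leafarea}
whole_plant_leaf_area(c(0, 380, 1e6), leaf_area_params("H"))
```

## Curve fitting

The fitting pipeline refits all four families from longitudinal
measurements (or synthetic series). For the logistic families the exponent
is linear in its coefficients once the amplitude is fixed —
`log(y_m/y − 1)` regresses on `(t², t, 1)` or on `log ts` — so the
amplitude is profiled over a log-spaced grid with an exact inner linear
solve, candidates are ranked by original-scale residual sum of squares,
the best is refined by 1-D minimization, and the result seeds a
Levenberg–Marquardt polish (`minpack.lm`) of the original residuals. The
heuristic start stated with each fitter (e.g. `y_m = 1.05·max(y)`,
`b = −1`) is tried as well and the better final fit wins. There is no
random restarting: fitting is deterministic given the data.

The double logistic has no joint printed objective, so the transition point
is a grid-searched hyperparameter (step 0.01 on normalized time); each
candidate fits the two branches independently by the same profiled least
squares and the smallest total rss wins. The whole-series single fit is
always computed and offered as a branch start, which guarantees the nesting
inequality `rss_double ≤ rss_single`. Exponent arguments are clipped at
±700 before exponentiation throughout; degenerate (constant) series are
flagged, never raised as errors.

**Identifiability.** Refitting noise-free synthetic series on dense grids
recovers every packaged parameter set to better than 0.1 % — the packaged
tables are exactly reproducible from their own curves. Under measurement
noise the picture splits: the extension and leaf-area parameters are robust
(median errors of a few percent at 5 %-of-range Gaussian noise), but many
of the published dry-mass parameterizations are *ridges* — amplitudes of
7–63 on series whose maximum is 1, compensated almost exactly by the
exponent constant. For such sets noisy refits recover the curve but not the
parameters (median parameter errors of tens of percent at the same noise
level), and no estimator can do better; users comparing refitted
coefficients against the printed tables should compare fitted curves, not
raw coefficients.

## Synthetic data

`generate_synthetic_series()` emulates the destructive-harvest protocol:
curve values on a time grid plus additive Gaussian noise clamped at zero
(lengths, areas and masses are non-negative), seeded and reproducible
without touching the global RNG state. It does *not* emulate several
features of the real data: between-plant variability (each real time point
is a different plant), heteroscedastic measurement error, or the survivorship
of ranks that appeared late. Passing recovery tests therefore demonstrates
correctness of the fitting machinery under the stated noise model, not
field-readiness of the parameter estimates.

## Light and carbon mode

The growth chamber is reconstructed as a box with Lambertian area emitters
on the two lateral walls and the back wall, standing in for the 39
wall-mounted fluorescent tubes, and two upward-facing virtual sensors above
the shelf positions. The interior dimensions were never published; we adopt
1.0 × 0.6 × 1.5 m with lamp strips spanning 0.2–1.5 m height and 0.05 m
lateral margins, and calibrated that geometry once so the two-sensor mean
reads the measured 150 µmol m⁻² s⁻¹ when the source exitance is the rated
330 µmol m⁻² s⁻¹. The "total output" is interpreted as the exitance of the
emitting surfaces: an interior sensor's reading is the exitance times the
cosine-weighted fraction of its hemisphere covered by emitting surface,
which is necessarily below 1, so splitting 330 across panels could never
reproduce 150. Sensor estimates converge as `1/sqrt(n_rays)` with the
standard error reported.

Leaves absorb by single interaction (absorptance 0.85, no rescattering),
with occlusion resolved by the nearest hit; seedling canopies are sparse
enough that multiple scattering would contribute little. Leaf
photosynthesis is the standard C3 minimum of the Rubisco- and electron-
transport-limited rates minus dark respiration, with Q10-style temperature
responses; stomatal conductance and leaf energy balance are deliberately
collapsed into a fixed intercellular CO₂ fraction (0.7 of ambient) and
`T_leaf = T_air`, and all parameters are generic literature values exposed
in `photosynthesis_params()`. The daily budget integrates gross
assimilation over the photoperiod, subtracts maintenance respiration
(proportional to standing dry mass, Q10 at the 24-h mean temperature) and
growth respiration (a `1 − Y_g` share of the positive net pool), and
converts the rest to dry mass; the books balance to machine precision by
construction, and that identity is what the tests check. Carbon gain does
*not* feed back into leaf extension — extension stays empirical, as in the
source model — so the mechanistic dry mass is a parallel accounting, not a
driver.

## Problem sizes and defaults used by the tests

Simulations in the test-suite run 30–60 days (the experiment lasted one
month); recovery tests use dense grids of 70–101 points, 50 noise
replicates at σ = 5 % of the response range, and fixed seeds; sensor
calibration checks use 10⁵ rays; the per-day ray budget of the carbon mode
defaults to 2 × 10⁴. These sizes were chosen as the smallest that make the
Monte-Carlo standard errors small against the tolerances being asserted.

## Known limitations

No internode or root growth, no branching, no organ-level sink competition
(a single whole-plant carbon pool), no spectral light, no vernalization or
starch storage, and no feedback from carbon to morphology. The rank
fallback beyond the measured table and the blade shape factor are modelling
choices a user can override but not avoid. The geometric and empirical
whole-plant totals are deliberately reported side by side and not
reconciled; their ratio is a useful diagnostic of how far the per-leaf
allometry and the whole-plant curves disagree.
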