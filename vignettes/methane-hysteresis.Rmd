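---
title: "Seasonal hysteresis in the emergent temperature sensitivity of wetland CH4 emissions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal hysteresis in the emergent temperature sensitivity of wetland CH4 emissions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Ecosystem-scale methane emissions (`F_CH4`, mg C m^-2 d^-1) from wetlands
and rice paddies broadly track temperature over a season, but the apparent
flux–temperature relationship is *emergent*: it integrates methanogenesis,
methane oxidation, transport, substrate supply, and hydrology. When daily
flux is plotted against daily air temperature over one growing season, many
sites trace a loop rather than a curve — at the same temperature, flux is
systematically higher after the seasonal temperature peak than before it.
This package quantifies that intra-seasonal hysteresis per site-year,
summarises it across a network of flux-tower sites, and asks how much of the
day-to-day flux variance a temperature-only model can capture once
ecosystem-type, site, year, and within-season variability are progressively
resolved.

```{r setup}
library(ch4hyst)
```

## The anchored quadratic branch model

The analysis window is the frost-free season: the longest run of days with
driver temperature above 0 °C in a site-year (alternative thresholds based
on GPP are available via `season_policy()`). The season is split at the day
of maximum seasonal temperature `T_max` into an *earlier* (warming) and a
*later* (cooling) branch. Each branch's emergent temperature response is a
quadratic constrained to pass through two anchors — the origin (zero flux
at 0 °C) and the measured flux at the temperature maximum,
`(T_max, F_Tmax)`:

$$F(T) = a_{hys}\,T^2 + \left(\frac{F_{T_{max}}}{T_{max}} - a_{hys}\,T_{max}\right) T$$

The two anchors force the earlier and later curves to meet at both ends, so
they enclose a closed loop, and leave exactly one free parameter per branch:
the curvature `a_hys` (mg C m^-2 d^-1 °C^-2), the *hysteresis parameter*.
Its least-squares solution is available in closed form
(`a = sum(x'y') / sum(x'^2)` with `x' = T^2 - T_max T` and `y'` the flux
after removing the anchored linear part); `fit_branch()` implements it and
`constrained_polyfit()` provides the general fixed-point polynomial fit used
for the functional-form robustness checks (orders 1, 2, 3, and 5, plus an
unconstrained Boltzmann–Arrhenius curve, via `compare_functional_forms()`).

Two loop statistics are computed per site-year:

* `H_A` (`hysteresis_area()`): the area between the later and earlier fitted
  curves over `[0, T_max]`, normalised by the maximum absolute fitted flux
  times `T_max`. The numerator has the closed form
  `(a_earlier - a_later) * T_max^3 / 6`; the denominator's maximum is found
  analytically (interval endpoints and each parabola's vertex). `H_A > 0`
  means a counterclockwise loop: more flux later at the same temperature.
* `H_mu` (`hysteresis_mean()`): mean measured daily flux of the later branch
  minus the earlier branch — deliberately computed from measured values, not
  fitted curves.

The apparent activation energy is fit per season by ordinary least squares
of `ln F` on `-1/(kT)` with the Boltzmann constant fixed at
8.62e-5 eV K^-1 (`fit_arrhenius()`); non-positive flux days cannot enter the
log and are excluded and counted.

## Tunable parameters and defaults

| Parameter | Default | Why |
|---|---|---|
| season threshold | driver > 0 °C | the frost-free season bounds the biologically active period across climate zones |
| `max_gap_days` | 3 | single start/end dates per season; strict contiguity on noisy daily air temperature would fragment seasons (set 0 for strict behaviour) |
| `min_season_days` | 30 | shorter runs give unstable branch splits |
| `min_days_per_branch` | 10 | prevents 1-parameter fits on a couple of points from dominating the distributions |
| `use_gapfilled` | `FALSE` | gap-filled fluxes are examined but excluded from fitting to avoid gap-filling artefacts |
| monthly coverage | 15 valid days | half-month coverage, a common flux-synthesis rule |
| intercept anchor | 0 at 0 °C | physical reference; `intercept_mode = "near_zero_mean"` instead anchors at the mean flux measured within ±0.5 °C, falling back to 0 when no such day exists |
| `H_A` denominator | max over fitted curves | follows the defining formula; a `measured_max` toggle normalises by the largest measured seasonal flux instead |

Deterministic conventions: ties at the temperature maximum resolve to the
earliest day; the `T_max` day belongs to the earlier branch (both curves are
anchored there anyway, so this only marginally affects `H_mu`); southern
(latitude < 0) site-years run 1 July–30 June so one austral season stays
contiguous; if flux is missing on the `T_max` day the anchor falls back to
the mean flux over the nearest (≤ 2 per side) season days within 1 °C of
`T_max`, and the site-year is skipped if none exist.

## The pooled model hierarchy

`evaluate_tiers()` compares seven models of daily flux on the same
prediction days. Six are pooled least-squares regressions whose fitting
groups are the cross-product of the variability factors they resolve —
none (`"T"`, one global curve), ecosystem type, site, site-year (`IAV`),
and seasonal branch (`ISV`). Pooled groups have no common anchors (the
anchors are site-year quantities), so each group gets a quadratic through
the origin with free linear and quadratic coefficients; an Arrhenius form is
available. Groups with fewer than 3 days, and groups unseen at prediction
time, inherit the fit of their parent group (factors dropped finest first:
ISV, IAV, site, type). Scoring is in-sample, matching the descriptive
intent: the question is how much variance each representation *can* absorb,
not out-of-sample skill.

Bias metrics use ratio-of-sums (`100 * sum|pred - obs| / sum(obs)` for
absolute bias; signed per-site-year branch bias analogously), which avoids
near-zero-flux denominators; per-day ratios would explode on shoulder-season
days.

The seventh, *hybrid*, model predicts each branch's `a_hys` with a
random-forest regression (`fit_ahys_regressor()`, via `ranger`) on ten
predictors — seasonal branch, branch-cumulative GPP and precipitation,
`T_max`, branch mean temperature, ecosystem type, latitude, site, site-year,
and `F_Tmax` — and plugs the prediction into the anchored quadratic, so at
`T_max` it reproduces the measured anchor exactly. Mean WTD, wind speed,
pressure, and calendar year are computed and stored but excluded by default
(limited predictive power); `include_extras = TRUE` restores them.

Forest configuration (logged in every fitted object): 500 trees, seed
20210415, `mtry` = half the predictor count, minimum node size 3,
permutation importance over 10 seeded shuffles per predictor. The
square-root `mtry` convention is a classification default; a regression
dominated by a few strong predictors needs a larger candidate draw, and
node size 3 is the usual regression setting. Categorical predictors are
label-coded as integers in order of first appearance — a deterministic
encoding whose codes survive unseen levels at prediction time (coded below
every training level); this matters for the leave-site-out holdout, which
must always be reported next to the in-sample error because site and
site-year identifiers make the in-sample fit near-perfect by construction
(`grouped_holdout_error()`).

## The synthetic data generators

Real flux-tower data require an external download, so every claim the test
suite makes is exercised on synthetic data with known ground truth. Two
generators are provided on purpose:

* **Parametric** (`gen_flux_parametric()`): inverts the anchored quadratic.
  Daily temperature is a seasonal sinusoid plus AR(1) noise
  (`gen_temperature()`); the season and its maximum are located with the
  same policy the analysis uses; earlier/later branch days get the model
  curve with injected `a_early`/`a_late`; multiplicative lognormal noise
  with a chosen CV is applied (flux magnitudes span orders of magnitude
  across sites, so additive noise would drown low-flux sites); off-season
  days get a small positive floor (N(0.5, 0.2^2) truncated at 0, keeping
  winter days non-informative without zeros breaking log plots). Noise-free
  generation followed by analysis returns the injected parameters to
  1e-9 — the exact-recovery surface.
* **Mechanistic** (`gen_flux_mechanistic()`): a substrate-pool model. A
  fraction of lagged GPP feeds a pool that decays into emission at a
  Q10-accelerated rate. Nothing about hysteresis is injected; positive
  `H_A` *emerges* because substrate accumulated before the temperature peak
  is emitted after it. This generator provides qualitative realism and an
  independent route to the headline sign.

`gen_network()` draws a multi-site network: sites cycle through the eight
ecosystem types (bog, fen, marsh, peat plateau, rice, salt marsh, swamp,
wet tundra), peak fluxes are lognormal (median 100 mg C m^-2 d^-1, sdlog
0.5) with type-specific multipliers spanning roughly 0.4–2, latitudes span
the boreal-to-temperate band, and per-site-year curvature pairs are drawn
so that a stated fraction (default 75%, the observed regime) is
positive-hysteresis by construction with a guaranteed minimum gap.
Curvatures are drawn in units of `f_peak / (t_mean + t_amplitude)^2`
(`a_units = "per_tmax2"`), which keeps seasonal fluxes predominantly
positive for any site's thermal range; the literal `U(-1, 1)`
mg C m^-2 d^-1 °C^-2 scale of the worked examples is available as
`a_units = "per_100"` and is used by the parameter-recovery preset
(`gen_network_preset("recovery", ...)`: 100 sites × 2 years, common peak
flux 100, 10% noise, independent uniform curvature draws).

What passing tests on these generators do *not* show: real data have gaps,
sensor drift, non-sinusoidal weather, water-table regime shifts, and
management events (rice irrigation and drainage), none of which are
emulated. The generators validate the estimators and the pipeline's
bookkeeping, not the ecological conclusions.

## Numerical choices

* `constrained_polyfit()` implements two algebraically equivalent routes:
  constraint elimination (interpolant through the fixed points plus a basis
  vanishing at them, solved by QR) and the Lagrange-multiplier KKT system.
  The second exists as a permanent internal cross-check of the first; the
  test suite holds them to 1e-9 agreement on randomised instances. Both
  routes map the abscissa affinely onto [-1, 1] before building Vandermonde
  matrices, and the KKT solve applies three steps of iterative refinement —
  without these, degree-5 fits on temperature-scaled data lose ~6 digits.
* Rank-deficient free designs drop the unidentifiable directions (zero
  coefficients) rather than erroring, matching `qr.coef` conventions.
* `H_A`'s integral and its denominator's maximum are evaluated in closed
  form; the tests verify both against 1e5-point trapezoidal integration.
* Degenerate inputs are typed conditions (`ch4hyst_no_season`,
  `ch4hyst_anchor_error`, `ch4hyst_insufficient_branch`,
  `ch4hyst_degenerate_fit`, ...) so network-level loops can skip-and-count
  rather than abort.
* Monthly-resolution analysis rescales the season threshold to months
  (ceiling of days/30.44, floor 3) and requires 3 entries per branch.

## Problem sizes used by the tests and acceptance script

Chosen as the package's own validation conditions: 1000 randomised
constrained-fit instances; 200 site-years (100 sites × 2 years) at 10%
noise for parameter recovery; a 48-site network (2–6 years per site) at 20%
noise for detection and the model-comparison table; 20 seeded replicate
networks of 10 sites for the tier-ordering check; 20 seeded forests of 200
rows for the importance check; 50 Latin-hypercube draws for the mechanistic
sign check.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_site_config(seed = 42, years = 2, a_early = 0.3,
                         a_late = -0.3, flux_noise_cv = 0)
sr <- gen_site(cfg)
res <- analyze_site_year(sr, site_meta("SY-001", "fen", 55), year = 2015)
res
#> <hysteresis_result> SY-001 2015 (t_air)
#>   H_A = +0.5910 (positive), H_mu = +60.9 mg C m-2 d-1
#>   a_earlier = +0.3, a_later = -0.3, Tmax = 25.8 degC, F@Tmax = 100
plot_hysteresis_loop(res)
```

## Known limitations

* In-sample tier scoring intentionally favours finer tiers; a
  site-year-holdout extension exists only for the hybrid regressor.
* The `H_A` normalisation follows the defining integral formula; the
  looser "maximum seasonal flux" normalisation is available as a toggle but
  the two differ when a fitted parabola overshoots the measured range.
* Half-hourly data, gap-filling itself, GPP partitioning, and unit
  auto-detection are out of scope: inputs are daily tables in the
  documented CSV dialect.
* Negative measured fluxes (uptake) are retained in quadratic fits but are
  necessarily excluded from Arrhenius fits; strongly methanotrophic seasons
  therefore have fewer Arrhenius-usable days.
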