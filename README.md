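# ch4hyst

Seasonal hysteresis in the emergent temperature sensitivity of wetland
methane emissions.

## What it is for

Eddy-covariance towers over wetlands and rice paddies measure daily
ecosystem CH4 emissions (`F_CH4`, mg C m⁻² d⁻¹) alongside air and soil
temperature, GPP, water-table depth, and precipitation. Plotted against
temperature over one frost-free season, `F_CH4` often traces a loop: at the
same temperature, emissions are higher after the seasonal temperature peak
than before it. `ch4hyst` is for flux-synthesis scientists who want to
quantify that intra-seasonal hysteresis per site-year, summarise it across
a site network, and measure how much better flux is predicted as
ecosystem-type, site, year, and within-season variability are progressively
resolved in the temperature-response model.

## The model at its core

Each frost-free season (days with driver temperature > 0 °C) is split at
the day of its temperature maximum `T_max` into an earlier and a later
branch. Each branch's emergent response is a quadratic forced through two
anchors — the origin and the measured flux at the maximum,
`(T_max, F_Tmax)`:

    F(T) = a_hys · T² + (F_Tmax / T_max − a_hys · T_max) · T

leaving one free curvature `a_hys` per branch (the hysteresis parameter,
mg C m⁻² d⁻¹ °C⁻²). Because both branch curves share the anchors they
enclose a closed loop, summarised by

* `H_A` — the enclosed area, `∫₀^Tmax (F_later − F_earlier) dT`
  normalised by the maximum absolute fitted flux times `T_max`
  (closed form: numerator `(a_earlier − a_later)·T_max³/6`);
* `H_mu` — mean measured daily flux, later branch minus earlier branch.

`H_A > 0` (counterclockwise loop) means more flux later in the season at
the same temperature. The package also fits Boltzmann–Arrhenius apparent
activation energies (`ln F = Ea·(−1/kT) + ε`, k = 8.62×10⁻⁵ eV K⁻¹), a
hierarchy of pooled flux–temperature regressions (universal → ecosystem
type → site → site-year → seasonal branch), and a hybrid model that plugs a
random-forest prediction of `a_hys` into the anchored quadratic. A
synthetic multi-site generator with controllable hysteresis makes the whole
pipeline testable without external data.

## A worked example

```r
library(ch4hyst)

# one synthetic site: injected curvatures +0.3 (earlier) / -0.3 (later)
cfg <- synth_site_config(seed = 42, years = 2, a_early = 0.3,
                         a_late = -0.3, flux_noise_cv = 0)
sr  <- gen_site(cfg)
analyze_site_year(sr, site_meta("SY-001", "fen", 55), year = 2015)
#> <hysteresis_result> SY-001 2015 (t_air)
#>   H_A = +0.5910 (positive), H_mu = +60.9 mg C m-2 d-1
#>   a_earlier = +0.3, a_later = -0.3, Tmax = 25.8 degC, F@Tmax = 100
```

The injected curvatures are recovered exactly (noise-free data), the loop
area is positive (later curve above the earlier one), and the mean daily
flux is 60.9 mg C m⁻² d⁻¹ higher after the temperature peak.

```r
# a 10-site network with 75% positive-hysteresis site-years by construction
net <- gen_network(n_sites = 10, seed = 7, years_range = c(2, 3))
an  <- analyze_network(net$data, net$meta)
an
#> <network_analysis> 25 site-years analyzed, 0 skipped
#>   positive H_A: 92.0% | positive H_mu: 84.0%

days     <- build_day_table(an)
training <- build_training_table(an)
reg      <- fit_ahys_regressor(training, n_trees = 200, seed = 7)
evaluate_tiers(days, hybrid = reg, training = training)
#> <tier_evaluation>
#>   T                  59.9% absolute bias (6109 days)
#>   T+type             34.9% absolute bias (6109 days)
#>   T+type+ISV         30.4% absolute bias (6109 days)
#>   T+site             27.5% absolute bias (6109 days)
#>   T+site+IAV         26.1% absolute bias (6109 days)
#>   hybrid             21.1% absolute bias (6109 days)
#>   T+site+IAV+ISV     15.8% absolute bias (6109 days)
```

A single global temperature curve mispredicts daily flux by ~60% of total
emissions; resolving site and within-season variability cuts that to ~16%,
and the hybrid (forest-predicted `a_hys`) model sits between the site-level
tiers — the qualitative tiering the model comparison is designed to expose.

Reading real data instead of generating it:

```r
sr  <- read_daily_table("JP-BBY.csv")          # FLUXNET-CH4 daily dialect
sr  <- apply_qc(sr, qc_policy(use_gapfilled = FALSE))
res <- analyze_site_year(sr, site_meta("JP-BBY", "fen", 43.3), year = 2015)
plot_hysteresis_loop(res)
```

Column conventions: `TIMESTAMP` (ISO or YYYYMMDD), `TA`, `TS_1`, `TS_2`,
`FCH4`, `FCH4_F` (gap-filled flux), `GPP`, `WTD`, `P`, `WS`, `PA`; missing
values as −9999 or empty; remappable via `col_map`. WTD is in cm, positive
above the soil surface. A directory of such files plus a site-metadata
table (`SITE_ID`, `TYPE`, `LAT`, `LON`) feeds the one-command harness:

```sh
Rscript inst/scripts/replicate.R --data daily_csvs/ --meta site_meta.csv --out replication/
```

which writes the per-site-year hysteresis summary, tier biases (overall and
per ecosystem type), branch-wise signed biases, and predictor importances.

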