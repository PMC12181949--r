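# smokeburden

Attribution of cardiorespiratory emergency-department (ED) visit burden to
all-source fine particulate matter (PM2.5) on smoke-stratified days, and
projection of that burden onto a hypothetical expanded prescribed-fire
program.

The package is written for air-pollution epidemiologists and fire/health
impact assessors who want a tested, reproducible implementation of the
smoke-strata burden-rate approach on ZIP-day panel data: daily ZIP-level
ambient PM2.5, dispersion-modelled wildfire and prescribed-fire smoke
PM2.5, and daily respiratory / cardiovascular ED counts. Because such
health records are restricted, a first-class synthetic-data module
generates seeded panels with the statistical structure the analysis
assumes, so every stage runs (and is tested) without any download.

## What it computes

**Health impact function (HIF).** Daily outcome counts follow a Poisson
log-linear model with distributed exposure lags,

    y_zt ~ Poisson(mu_zt)
    log mu_zt = log(pop_z / 1e5) + alpha_z + sum_l beta_l * x_{z,t-l} + gamma' w_zt

with per-ZIP intercepts `alpha_z`, confounders `w` (annual harmonics,
calendar-year and day-of-week indicators, temperature, relative humidity),
and aPM2.5 `x`. The cumulative log relative risk per ug/m3 is
`beta = sum_l beta_l`, reported as the familiar percent change per
10 ug/m3, `100 (exp(10 beta) - 1)`, with a Wald 95% CI; the lag window is
chosen by BIC. Respiratory effects act over lags 0-4, cardiovascular
effects on the same day.

**Attributable burden.** Each ZIP-day's excess visits are
`y (1 - exp(-sum_l beta_l x_{t-l}))` (the attributable-fraction excess
form). Days are classified by fire type (none / wildfire / prescribed /
both) and into smoke concentration strata
(0; 0.01-0.05; ...; 150.01+ ug/m3), person-day exposure is accounted per
stratum, and strata-specific daily burden rates per 100,000 are computed
by a three-step average (ZIP-stratum daily mean, per-capita scaling,
unweighted mean over ZIPs).

**Scenario comparison.** Historical per-ZIP burden rates are applied to
projected future prescribed-fire smoke days matched by day of the year;
subtracting each ZIP's zero-smoke counterfactual on its smoke days yields
annual prescribed-fire-attributed burden rates for both periods and their
per-ZIP difference (difference-in-difference).

## Worked example

```r
library(smokeburden)

cfg <- pipeline_config(
  generator = generator_config(n_zips = 40, start_date = "2008-01-01",
                               end_date = "2010-12-31", seed = 2024),
  lag_candidates = list(respiratory = c(0L, 4L), cardiovascular = c(0L, 0L)),
  n_cycles = 8, burn_days_per_zip = 40)
bundle <- run_pipeline(cfg)

glance(bundle$hif_respiratory)[, c("pct_per10", "ci_low", "ci_high", "baseline_rate")]
#>   pct_per10 ci_low ci_high baseline_rate
#> 1      2.93   2.18    3.69          11.9
glance(bundle$hif_cardiovascular)[, c("pct_per10", "ci_low", "ci_high", "baseline_rate")]
#>   pct_per10 ci_low ci_high baseline_rate
#> 1     0.726  0.320    1.13          13.0
```

The fitted percent changes per 10 ug/m3 aPM2.5 (2.93 respiratory, 0.73
cardiovascular) bracket the truths this synthetic panel was generated
with (2.27 and 0.89) within their CIs; baseline rates land near the
configured 11.5 / 12.6 visits per 100,000 per day.

```r
bundle$burden_tables$none
#>   group stratum daily_rate_per_100k n_zip_days n_zips
#> 1 none  0                     0.415      38142     40
head(bundle$burden_tables$prescribed, 2)
#>   group      stratum   daily_rate_per_100k n_zip_days n_zips
#> 1 prescribed 0.01-0.05               0.507        101     30
#> 2 prescribed 0.06-0.10               0.549        109     38
```

On zero-smoke days this panel carries an aPM2.5-attributed
cardiorespiratory rate of 0.415 per 100,000 per day; low-concentration
prescribed-fire days sit slightly above it, because ambient PM2.5 is
higher in the seasons and places where prescribed fire occurs.

```r
head(bundle$result, 3)
#>   zip_id historical_rate future_rate in_both difference
#> 1 Z0001            3.35         3.49  TRUE        0.146
#> 2 Z0002            1.41         1.55  TRUE        0.140
#> 3 Z0003            4.01         3.26  TRUE       -0.749
mean(bundle$result$difference)
#> [1] 1.03
```

`difference` is each ZIP's change in annual prescribed-fire-attributed
visits per 100,000 between the future scenario (8 cycles, 40 smoke days
per ZIP-cycle at low concentrations) and the historical period — here the
extra low-concentration smoke days raise the average ZIP's annual
attributed burden by about 1 visit per 100,000.

The packaged annual exposure reference table is available directly:

```r
rx  <- reference_person_days("rx")
frx <- reference_person_days("frx")
exposure_ratio(frx, rx)            # ~14.9: future-vs-historical person-days
exposure_ratio(frx, rx, above = 5) # ~8.7 at concentrations above 5 ug/m3
```

Plot helpers: `plot_person_days()`, `plot_burden_rates()`, and
`autoplot()` on a scenario result.

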