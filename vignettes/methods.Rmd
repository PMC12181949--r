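---
title: "Methods: smoke-stratified PM2.5 burden estimation and scenario projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smoke-stratified PM2.5 burden estimation and scenario projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokeburden)
```

## The problem

Prescribed (intentional, managed) burning is expanding as a wildfire-risk
mitigation strategy. Smoke from both wildfire and prescribed fire adds
fine particulate matter (PM2.5) to ambient air, and short-term PM2.5
exposure is an established risk factor for cardiorespiratory morbidity.
The question this package operationalizes: if prescribed burning is
scaled up — many more smoke days, mostly at low concentrations, in more
populated places — how does the PM2.5-attributable emergency-department
(ED) visit burden change relative to the historical pattern of fewer,
sometimes more intense, prescribed-fire smoke days?

The unit of analysis is the ZIP-day. Inputs are daily ZIP-level ambient
all-source PM2.5 (aPM2.5, ug/m3), dispersion-modelled wildfire (WF) and
prescribed-fire (Rx) smoke PM2.5, temperature, relative humidity,
population, and daily respiratory and cardiovascular ED counts. A future
scenario supplies projected prescribed-fire smoke (fRx) ZIP-days over
repeated annual cycles of a single representative meteorological year.
Because record-level health data are restricted, the package ships a
synthetic generator that emulates these inputs; all statistical machinery
is exercised against it.

## Health impact function

For outcome counts $y_{zt}$ (ZIP $z$, day $t$) the model is Poisson with
log link,

$$\log \mu_{zt} = \log(\mathrm{pop}_z/10^5) + \alpha_z
  + \sum_{l=0}^{L}\beta_l\, x_{z,t-l} + \gamma' w_{zt},$$

where $x$ is aPM2.5 and $w$ collects the time-varying confounders. The
cumulative log relative risk per ug/m3 is $\beta=\sum_l \beta_l$; the
reported effect is the percent change per 10 ug/m3,
$100\,(e^{10\beta}-1)$, with a Wald 95% interval from the
linear-combination variance $\mathbf{1}'V\mathbf{1}$ of the lag block.
Assumptions: counts are conditionally independent Poisson given the
covariates (a negative-binomial switch exists in the generator for
robustness checks, not in the fitter, which would then be a
quasi-likelihood exercise); the concentration-response is log-linear over
the observed concentration range; confounding is captured by smooth
seasonality, weekday structure, temperature and humidity, and ZIP-level
intercepts.

Defaults and their reasons:

* **Lag structure** — unconstrained distributed lags, one coefficient per
  day, because nothing constrains the within-window shape; candidate
  windows default to `[0,0]` and `[0,4]`, and the window is chosen by BIC
  with ties broken toward the shorter window. Respiratory effects are
  conventionally acute-cumulative (lags 0-4), cardiovascular same-day;
  the defaults reflect that.
* **Per-ZIP intercepts** — fixed effects, not random. At panel scale the
  fixed-effects rate-ratio estimator is consistent and deterministic, and
  it avoids distributional assumptions on the intercepts. An exchangeable
  random-intercept mode (`method = "ranef"`, via lme4) is provided for
  sensitivity analysis.
* **Seasonality** — one annual sine/cosine pair plus calendar-year
  indicators (`confounder_spec(harmonics = )` raises the pairs).
  Temperature and humidity enter linearly; their generator effects are
  linear, and at desk scale spline bases add variance without changing
  the exposure coefficient.
* **Offset** — log population per 100,000, so intercepts read as log
  daily rates per 100K. Scaling every population by a constant leaves the
  exposure coefficients unchanged (tested).

### Fitting with many ZIP intercepts

With hundreds of ZIPs, explicit intercept dummies are wasteful. The
default fitter (`method = "absorb"`) runs IRLS in which each weighted
least-squares step eliminates the intercept block exactly by weighted
within-ZIP centering of the design and working response; the slope
covariance is the inverse centered weighted cross-product (the Schur
complement of the intercept block), so standard errors account for
intercept estimation. This is the joint maximum-likelihood fixed-effects
fit — the test suite verifies agreement with the explicit-dummy
`glm.fit` route to ~1e-8 on shared panels — at a fraction of the memory.
Numerical guards: the linear predictor is clamped at 30 (rate ratios
beyond e^30 indicate corrupt inputs, not signal) and convergence is
declared on relative deviance change below 1e-10 (50 iteration cap, with
a warning if unmet).

### Lag-window selection

Candidates fit on different post-trim samples have incomparable
likelihoods (dropping each ZIP's first `L` days removes rows), so
`select_lag_window()` trims every candidate by the largest candidate lag
and computes BIC $=-2\ell + k\log n$ on that common sample, with $k$
counting slope columns plus ZIP intercepts and $n$ the common post-trim
ZIP-day count. On generator panels, whose cardiovascular truth is
same-day only, the `[0,0]` window wins the BIC comparison in the large
majority of seeds (tested).

## Smoke strata and exposure accounting

Concentrations are rounded to two decimals half-away-from-zero and
matched to closed intervals: 0 (the zero-smoke stratum), 0.01-0.05,
0.06-0.10, 0.11-0.25, 0.26-0.50, 0.51-1.00, 1.01-5.00, 5.01-10.00,
10.01-15.00, 15.01-20.00, 20.01-50.00, 50.01-100.00, 100.01-150.00,
150.01+ ug/m3. Rounding first makes the listed closed intervals an exact
partition of the nonnegative reals; binning is monotone (tested). A
collapse-to-`50.01+` view mirrors published tables whose top bin pools
everything above 50 ug/m3 (historical maxima: 1120 wildfire, 253
prescribed fire). A ZIP-day's fire type is none / wildfire / prescribed /
both according to which smoke sources bin above zero.

Person-day accounting sums ZIP population over qualifying ZIP-days per
stratum and source. Each source's table conditions only on its own
concentration, so a "both" day contributes to both the WF and Rx tables;
shares are computed over non-zero (smoke) strata. Historical totals
annualize by the number of years, future totals by the number of cycles.
The packaged reference table (`reference_person_days()`) carries an annual
person-day exposure accounting for the four sources; recomputing its
printed shares from the person-day cells agrees to ±0.1 percentage
points, and its headline fold-ratios (future-vs-historical prescribed
fire ≈ 15 overall, ≈ 8.7 above 5 ug/m3) are exercised in the acceptance
tests.

## Attributable burden

Excess visits on a ZIP-day are
$y\,(1 - e^{-\sum_l \beta_l x_{t-l}})$ — the standard excess
(attributable-fraction) form; a linearized variant
$y\sum_l\beta_l x_{t-l}$ is available for comparison. The cumulative
effect is distributed over lags with the fitted per-lag coefficients (not
re-normalized), so attribution matches the fitted model exactly. Days
whose lags predate the series use the ZIP's first concentration as the
lag value, so the ledger covers every panel day; attribution is zero
whenever concentrations are zero, and never exceeds the observed count.

Strata-specific daily burden rates follow a three-step computation on
cardiorespiratory (respiratory + cardiovascular) attributable counts:
(1) per ZIP and stratum, total attributable visits divided by days in the
stratum; (2) divided by ZIP population, times 100,000; (3) unweighted
mean over ZIPs with at least one day in the stratum. Strata with no days
are omitted rather than reported as NaN. Rates stay real-valued
throughout; rounding is a display concern.

## Counterfactual and scenario comparison

The zero-smoke counterfactual of a ZIP is its mean daily attributable
rate (per 100K) over fire-type-none days, with a statewide fallback (mean
of per-ZIP means) for ZIPs that never see a smoke-free day. The annual
prescribed-fire-attributed rate sums, over prescribed-fire-impacted days
(including "both" days by default; a flag restricts to Rx-only), the
difference between attributed visits and the counterfactual expectation,
scaled per 100K per year. Negative day-level differences are retained —
truncation would bias the estimator upward; clamping belongs in display.

The future scenario receives historical rates matched by day of the year:
each projected smoke ZIP-day gets the mean over historical years of that
ZIP's attributed rate on the same calendar day (Feb 29 maps to Feb 28),
converted to a count via population, labelled with its fRx stratum, then
aggregated with the same three-step and annual-rate machinery. The
difference-in-difference is simply future minus historical per ZIP.

Identity checks: with a single-year history the day-of-year mean is the
day's own rate, so projecting the historical period onto itself must give
a difference of exactly zero — the tests assert this to 1e-10 on a
non-leap year, where day-of-year matching is a bijection (with a leap
year in the history, Feb 28/29 average together by design and the
identity holds only up to that pooling).

## The synthetic generator

`generate_panel()` emulates the data products the analysis consumes, not
the physics that produced them (no plume dispersion, no GIS, no
meteorological reanalysis — those are upstream of this package's scope):

* **Ambient background** — a winter-peaking sinusoid around 9.11 ug/m3
  (amplitude 2.5) with gamma day-to-day noise (sd 6), plus the smoke
  components; daily values are nonnegative by construction and correlate
  positively with smoke on smoke days.
* **Smoke** — episodic block events per ZIP: Poisson event counts
  (8 wildfire, 10 prescribed-fire events per ZIP-year), start days
  weighted toward June-September (wildfire) or November-January
  (prescribed), geometric durations (means 4 and 2 days), lognormal peak
  intensities (log-means log 8 and 0, log-sds 1.4 and 1.2) with
  geometric decay 0.6/day. Peaks truncate at the historically observed
  maxima (1120 and 253 ug/m3): an untruncated lognormal tail occasionally
  stacks events into physically meaningless thousands of ug/m3, which
  both corrupts the Poisson counts and stresses the fitter far outside
  the supported concentration range.
* **Counts** — Poisson with log mean = log(baseline x pop/1e5) + ZIP
  intercept (sd 0.15 on the log scale, mean offset by -sd^2/2 so expected
  rates equal the baselines 11.5 / 12.6 per 100K) + a small seasonal
  log-cycle (amplitude 0.05) + day-of-week offsets + linear temperature
  and humidity effects + the injected concentration-response: 2.27% per
  10 ug/m3 distributed uniformly over lags 0-4 for respiratory, 0.89% at
  lag 0 for cardiovascular.
* **Future scenario** — per ZIP-cycle, a seeded set of burn days in a
  single non-leap representative year (2014), November-January weighted,
  with lognormal fRx intensities (log-mean log 0.3, log-sd 1.1) putting
  over 99% of the mass below 5 ug/m3 — frequent low-concentration
  exposure, the scenario's defining feature.
* **Seeding** — one master seed; each ZIP (and each ZIP-cycle in the
  scenario) draws from its own deterministic substream, so enlarging a
  panel never perturbs previously generated ZIPs, and identical configs
  produce byte-identical panels.

What the generator does **not** emulate: spatial correlation of smoke
plumes across ZIPs (events are independent per ZIP), within-ZIP temporal
autocorrelation of counts beyond the covariates (conditional
independence), exposure measurement error, outcome misclassification, and
demographic structure. Passing tests therefore demonstrate the
correctness and calibration of the estimators under the model's own
assumptions — not robustness to the violations real data would bring.

## Problem sizes and calibration checks

The recovery experiment fits 50 replicate panels of 100 ZIPs x 3 years
and requires the injected truths to fall inside the fits' own 95%
intervals in at least 90% of replicates (observed: 96% respiratory, 98%
cardiovascular). The acceptance script uses a single panel of 500 ZIPs
over the 9-year study window for effect recovery — enough person-time
that the sampling error of the recovered percent changes is a few
hundredths of a point — and 200 ZIPs x 2 years with all effects switched
off for the baseline-rate calibration (Monte-Carlo spread ≈ 0.1 per
100K). These sizes are the package's own precision choices; the
generator's epidemiological parameters are never adjusted per run.

## Known limitations

* The fitter is strict Poisson; with overdispersed real counts its CIs
  would be anticonservative (use the random-intercept mode or treat CIs
  with care).
* Attribution assumes the fitted log-linear response extrapolates across
  the whole observed concentration range, and that smoke-derived and
  other ambient PM2.5 are equally potent per ug/m3.
* Day-of-year matching transfers historical rates to the scenario without
  re-modelling — it inherits whatever confounding structure the
  historical rates carry on those calendar days.
* The scenario comparison ignores population change, behavioural
  adaptation, and any wildfire reduction benefit of prescribed burning;
  it isolates the exposure-pattern change only.
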