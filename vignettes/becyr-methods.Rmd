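---
title: "Methods: the BECYR yield response model and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the BECYR yield response model and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(becyr)
```

## The model

`becyr` estimates a quadratic county fixed-effects response of annual crop
yield (bushels/acre) to climate, economic and atmospheric drivers on a
county-year panel:

$$
Y_{t,c} = \alpha_c
  + \sum_i \beta_i x_{i,t,c}
  + \sum_i \gamma_i x_{i,t,c}^2
  + \theta\,(PRECI_{t,c} - \overline{PRECI})(DD_{t,c} - \overline{DD})
  + e_{t,c}
$$

with regressors $x$: pre-season precipitation (*PBGS*, mm), growing-season
precipitation (*PRECI*, mm), growing-season degree days above 10 °C
(*DD*), the one-year-lagged real crop price, the real fertilizer price
index, an integer time trend, and growing-season CO₂ (ppm) — the last
entering not at all, linearly, or quadratically depending on the model
variant. The county intercepts $\alpha_c$ absorb time-invariant local
factors (soil, topography, groundwater); there is no global intercept.
Squares are of the *raw* variables; only the precipitation-by-degree-days
interaction is centered, at the grand means over all counties and years,
which reduces its collinearity with the main effects without changing the
fitted surface (the county indicators span the constant; see the centering
invariance test).

Assumptions worth stating plainly: county effects are constant over time;
all slope coefficients are common across counties; errors may be
heteroskedastic and serially dependent within county but are treated as
independent across counties. The default covariance estimator is
county-cluster robust (HC1 small-sample correction); a panel Newey–West
kernel (default lag 2) and the classical estimator are alternatives. The
reported F statistic is the classical residual-sum-of-squares comparison
of the full model against the county-indicators-only model; adjusted R² is
computed about the grand mean so that values are comparable across
parameterizations despite the no-intercept design.

## Growing seasons and climate regressors

The growing season of a county-year is the frost-free window: it starts
the day after the last spring occurrence of daily *minimum* temperature at
or below −2.2 °C and ends the day before the first fall occurrence. Two
choices here were genuinely open and are parameters:

* **Which temperature carries the frost test.** We use `tmin`: a −2.2 °C
  event is conventionally a daily-minimum (radiative frost) event.
  `frost_threshold` is exposed for sensitivity work.
* **Where spring ends and fall begins.** The split day defaults to
  day-of-year 183 (July 1); any mid-summer day gives identical results in
  a temperate climate since frosts never occur there.

Fallbacks: a year with no spring frost starts January 1; no fall frost
ends December 31. Degree days accumulate `max(0, tmean − 10)` over season
days — daily means directly, with no sub-daily sine/triangle refinement,
matching the accumulation form stated for the original data. Pre-season
precipitation sums the 92 days (≈ three months) before the season start; a
calendar-month variant (the three whole months preceding the start month)
sits behind `calendar_months = TRUE`. The window may reach into the
previous calendar year, which is why the pipeline simulates (or expects)
one leading year of weather; a first-year row whose window is uncovered is
dropped and logged rather than silently imputed.

Missing daily records: up to 5 missing or NA days per county-year are
filled by linear interpolation; more is an error. The original analysis
used interpolated climate surfaces with complete coverage, so this policy
only matters for degraded inputs.

## The CO₂ proxy

Local CO₂ observations are assumed available only late in the study
period, while a distant reference station (tropical; opposite seasonal
phasing, smaller seasonal range) covers the whole period. The proxy model
is a least-squares fit of

$$\mathrm{ppm}_{target} = b\,\mathrm{ppm}_{reference} + a_{month(t)}$$

— one shared slope and twelve monthly intercepts, no global intercept. A
single slope (rather than twelve) is used because the relationship being
exploited is the shared long-run trend; the monthly intercepts absorb the
phase difference. Pearson correlations per calendar month over the overlap
serve as a screening table first. Reconstruction applies the fitted
coefficients to the reference record; observed months always take
precedence over proxy months when both exist ("observed overrides proxy").

Season-level CO₂ is the day-weighted mean of the monthly values over the
months the season intersects (weights = days of each month inside the
season). Whether the original aggregation was day-weighted or whole-month
is not documented; day-weighting is the choice here because it changes
continuously as season boundaries move. Since seasons are detected per
county but CO₂ is a single provincial series, `provincial_season()`
averages county start/end dates per year (rounded to whole days).

## Panel assembly

* Boundary changes: merged counties get the harvest-area-weighted mean
  yield, applied retroactively; total production is conserved exactly.
* Prices: monthly nominal prices are averaged to annual (unweighted),
  deflated by CPI to 2002 dollars, scaled by 1/100, and lagged one year —
  planting-time expectations are last year's price. The fertilizer index
  is quarterly, averaged to annual, deflated, and scaled by 1/100. The
  1/100 scales put the regressors in the units implied by the reference
  coefficients (a fertilizer-index turning point near 160 on the 100-based
  scale corresponds to 1.6 in model units).
* Trend: integers from 1 in the first panel year (1..55 for 1959–2013).
* Soybean filters: county-years with harvest area below 1,500 acres are
  dropped; then each county's leading years are dropped up to its last
  gap, so every retained county is gap-free through its final year. "Until
  no data were missing" admits several readings; the gap-free-suffix rule
  is the one implemented, every exclusion is logged with a reason, and the
  filter is idempotent.

## The synthetic test bed

`simulate_panel()` generates every input the pipeline consumes, with the
statistical structure the analysis assumes, so the full path from daily
weather to coefficient tables runs offline with known truth. What it
emulates — and what it does not — determines what a passing test means.

**Weather.** Daily mean temperature is an AR(1) anomaly (persistence 0.7,
marginal sd 3.8 °C) around a sinusoid (mean 6.5 °C, amplitude 14 °C,
upward crossing at day 110), with a slow warming drift of 0.15 °C per
decade; daily minimum sits 5 °C below the mean plus noise; precipitation
is Bernoulli(0.4)–gamma(0.8, scale 9 mm). These defaults were chosen once
to reproduce the stated study climatology: mean season start in late April
(day ≈ 114), end in mid-October (day ≈ 286), season precipitation ≈ 500 mm,
degree days ≈ 1 170. Not emulated: spatial correlation between counties
(each county draws independent weather), extreme-event clustering, and any
trend in precipitation. Tests passing on this generator therefore say
nothing about cross-county dependence in real data — the cluster-robust
covariance is exercised by the within-county AR(1) noise option instead.

**CO₂.** The reference series is a linear trend (1.55 ppm/yr from 315 ppm)
plus a harmonic peaking in May; the target adds monthly offsets with a
larger seasonal range, a November–April plateau and a mid-summer trough,
plus noise (sd 0.8 ppm) — exactly the form the proxy regression assumes,
which makes it a truth-known test bed for that module specifically.

**Economics.** Real prices decline over the period (corn 4.2 → 2.2 in
hundreds of 2002 dollars/tonne) with AR(1) fluctuation; the real
fertilizer index declines from 1.55 to 0.95 with a 1970s-style bump; CPI
grows at 3.9 %/yr through 100 in 2002. These give the attribution module
drifts of realistic sign and size (declining real prices, rising CO₂).

**Yields.** Computed exactly from the model applied to the realized
regressors — centering at the realized sample means of the returned panel —
plus configurable noise: i.i.d. Gaussian (default), AR(1) within county,
or variance proportional to the noiseless yield. The generating
coefficients default to the reference linear-CO₂ estimates, and the county
intercepts are an even spread chosen so mean yields are crop-typical
(≈ 100 bu/ac corn, ≈ 38 bu/ac soybeans). The original analysis reports no
residual variance; the default noise sd (16 corn, 7 soybeans) was set so
the refit adjusted R² lands at the reference values (≈ 0.79 / 0.65), which
is the only sense in which "study-scale noise" is defined here.

**Unbalancedness.** For soybeans, a configurable fraction (default 0.3) of
county-years before 1996 is dropped at random and harvest areas ramp up
logistically, so small-area early records exist for the area filter to
catch. A 2001 pest-year shift (default −11 bu/ac, matching the reference
dummy) is applied through the dummy's generating coefficient.

## Response quantities

* **CO₂ turning point**: $-\beta_{CO_2}/(2\gamma_{CO_2})$, a minimum when
  $\gamma_{CO_2} > 0$. A linear-CO₂ fit yields an explicit
  "no turning point" result rather than a number.
* **Peak moisture/heat**: for precipitation conditioned on degree days at
  level $d$, $-(\beta_2 + \theta(d - \overline{DD}))/(2\gamma_2)$, and
  symmetrically. At the grand mean this is $-\beta/(2\gamma)$ — the
  neutral default; conditioning on a recent warm window (e.g. 2009–13
  means) moves the peaks upward when $\theta > 0$ and $\gamma < 0$.
* **Linear CO₂ effect**: $100\,\beta_{CO_2}/\bar Y$ % per ppm with a
  ±1.96 SE interval scaled identically.
* **Attribution**: no formula is documented for "change attributable per
  year in average", so the default here is (marginal effect at sample
  means) × (OLS drift of the variable's annual mean on year), divided by
  the mean fitted first-year yield. Precipitation and degree days are
  reported jointly, adding $\theta$ times the drift of the centered
  product, because the interaction ties their marginal effects together. A
  year-on-year finite-difference variant is available behind
  `method = "finite-difference"`. Note that with trend–CO₂ correlation
  near 0.99 the *split* between those two entries is fragile in any
  variant — their sum is the stable quantity, which is why the diagnostic
  VIFs are part of the fit output.

## Validation machinery

`holdout_validate()` refits on the panel minus held-out years or counties
and reports RMSE and mean error; held-out counties have no estimated
intercept, so predictions use the mean county effect and are flagged. The
default hold-out is the last five panel years, mirroring the recent-window
focus of the response analysis — but note that late-year hold-outs are
partial extrapolations in trend and CO₂, so their RMSE exceeds the noise
sd; interior-year hold-outs recover it. `recovery_study()` repeats
simulate → assemble → fit and reports per-coefficient bias and nominal-95 %
coverage using the robust standard errors.

## Numerical choices and problem sizes

Estimation is QR-based through `lm` on the explicit design; the design
builder rejects zero-variance columns and rank-deficient fits are an error
naming the offending columns. VIFs are computed on within-transformed
(county-demeaned) linear terms, so they condition on the fixed effects the
way the estimator does; perfect collinearity reports `Inf` rather than a
large number. Turning points and peaks are closed forms; a zero quadratic
coefficient returns an explicit degenerate result. Noiseless-recovery
tests use a tolerance of 10⁻⁶ on the standardized scale (coefficient error
× regressor sd / yield sd).

Test problem sizes: module tests run 3–6 counties over 10–20 years;
structural end-to-end checks run the full 29 × 55 study once noiselessly
and 200 replicates at study-scale noise for interval coverage; oracle
equivalence uses 1,000 random small instances. These sizes were chosen so
Monte-Carlo assertions are stable at fixed seeds.

## Known limitations

* No spatial correlation in the generator, so cross-county dependence in
  robust inference is untested against truth.
* The boundary-change map is exercised synthetically; reconstructing a
  real jurisdiction's merge history is out of scope.
* The proxy model assumes the target–reference relationship is stable over
  the reconstruction period — untestable by construction, inherited here.
* Attribution semantics ("average per-year change") are one defensible
  formalization; the finite-difference variant exists to gauge
  sensitivity.
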