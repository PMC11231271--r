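# carbonsplit

Black carbon (BC) is a chemically stable combustion aerosol, which makes its
ambient concentration a usable tracer of combustion activity — if two large
confounders are removed. Day-to-day weather dilutes or concentrates whatever
is emitted, and several source sectors (vehicle exhaust, industry, biomass
burning) emit BC at once. `carbonsplit` implements the inference chain that
turns daily pollutant and meteorology time series into a
*transport-attributed* BC emission proxy, and then asks how epidemic waves
and quarantine policy shifted private versus public transport usage. It is
aimed at air-quality and environmental-epidemiology researchers working with
daily urban monitoring data.

## The method

1. **Weather normalization.** A random forest learns

   `Pollutant = f1(Year, Month, Whole, Meteorology) + ε`

   where `Whole` is days elapsed (a continuous local-emission trend term)
   and `Meteorology` is the eight-variable daily weather vector (U10, V10,
   D2M, T2M, BLH, MBLD, SP, TP). The normalized series is the mean
   prediction over meteorology rows resampled from the whole record, a
   counterfactual average that strips dispersion-driven variability while
   the time features keep the emission signal. Monte-Carlo spread across
   resamples gives a per-day uncertainty.

2. **Trend and baseline.** The normalized series is detrended by OLS
   (slopes reported per decade, 3652.5 days) and expressed against
   per-calendar-month baselines computed from the pre-pandemic years only.

3. **Source attribution.** Normalized nitrate (co-emitted with transport
   NOx) and sulfate (co-emitted with industrial SO2) act as tracers. A
   forest learns `BC_norm = g(NO3_norm, SO4_norm)` and two-sided
   counterfactual differences against low-quantile reference tracer values
   split the prediction into `BC_Transport + BC_Factory + floor`, exactly
   additive by construction. Because urban buses and metro are electric,
   `BC_Transport` is read as a private-transport proxy (`BC_Private`).

4. **Transport statistics.** Day-of-week metro statistics (population SD,
   2 dp) with a Welch workday/weekend test; percent changes of monthly
   volumes against matched-calendar-month baselines; and regime-wise OLS of
   monthly `BC_Private` on public-transport volume — positive coupling
   before the pandemic era, negative inside it.

5. **Epidemic response.** A regularized random forest on the monthly panel,
   `BC_Private = f3(Met, Period, Transmission, Fatality, Case)`, with
   partial-dependence curves and permutation significance tests for the
   epidemic covariates.

No observational inputs ship with the package; a synthetic scenario
generator (`simulate_scenario()`) reproduces the statistical structure the
chain assumes — multiplicative dispersion on additive sources, tracer
co-emission, outbreak suppression of transport volumes, regime-dependent
coupling — with known ground truth, so every stage is testable end to end.

## Worked example

```r
library(carbonsplit)

# published 45-day metro table: day-of-week statistics
day_of_week_stats(metro_daily_table())
#> # A tibble: 7 x 4   (weekday  n  mean    sd)
#> ...
#> workday 1.47 (sd 0.55, n 31) vs weekend 1.43 (sd 0.51, n 14)
#> Welch t = 0.188, two-sided p = 0.852

# full synthetic pipeline
report <- run_pipeline(default_config(seed = 1))
report
#> <carbonsplit_report>
#>   stages: simulate, normalize, trend, baseline, attribute, stats, respond
#>   normalized BC trend: -1.85 ug/m3 per decade
report$stats$segments      # per-regime slopes of BC_Private on public volume
report$stats$percent_change
```

The day-of-week table reproduces the published means and population SDs at
two decimals (Sunday 1.15 ± 0.33, workday 1.47 ± 0.55 million passengers)
and the Welch p = 0.85 confirms workdays and weekends are statistically
indistinguishable, which justifies treating monthly volumes as
representative of daily usage. On the default scenario the normalized BC
trend recovers the configured emission decline (about −1.8 µg m⁻³ per
decade), outbreak windows show metro volume decreases near 16/30/49 % and
the regime regressions recover coupling slopes near +0.03 and −0.17 µg m⁻³
per million passengers.

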