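---
title: "Methods: weather normalization, source attribution and pandemic mobility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weather normalization, source attribution and pandemic mobility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(carbonsplit)
```

## The model chain

Ambient black carbon is decomposed as

    BC = BC_Biomass + BC_Factory + BC_Transport + BC_Meteorology + ε

Three of the terms are emissions; the meteorology term is not an emission
but the modulation of all of them by dispersion. The package treats that
modulation as multiplicative — concentration = (sum of emissions) ×
dispersion factor + noise — because the stated physical mechanism is
dilution by wind and boundary-layer growth, and because a multiplicative
factor gives the synthetic generator a well-defined recovery target. The
normalization procedure itself (averaging model predictions over resampled
weather) is agnostic to this choice.

The chain is: (1) weather-normalize BC, nitrate and sulfate with one
forest per species; (2) fit and remove the long-run linear trend of
normalized BC; (3) split normalized BC into transport- and
factory-attributed parts using the two tracers; (4) relate the monthly
transport part (`BC_Private`) and the transport volumes to epidemic
covariates.

Biomass burning is handled indirectly: burning decisions correlate with
dry weather, so coupling the synthetic spike process to low precipitation
makes weather normalization absorb most of the biomass term, mirroring the
argument that removing meteorological impacts also removes biomass-burning
impacts.

## Weather normalization

`fit_met_model()` fits a `ranger` regression forest of the daily
concentration on `year`, `month`, `whole` (days since the first
observation — the continuous stand-in for slowly varying local emission)
and the eight meteorology variables. `normalize_pollutant()` replaces the
meteorology of every day `n_samples` times (default 200) with complete
rows drawn uniformly with replacement from the training record and
averages the predictions. Rows are resampled jointly: sampling columns
independently would fabricate physically impossible weather (e.g. a dew
point above the air temperature) and break the inter-variable covariance
the forest was trained on.

Choices worth knowing:

* Forest size 300 trees, minimum leaf 5, default `mtry`. Daily records of
  2–8 years (hundreds to thousands of rows) do not support more
  aggressive settings, and all values are pinned in the configuration for
  reproducibility.
* Day-of-week is **not** a default feature: the time terms are year,
  month and the continuous trend. A `use_dow` toggle exists because
  traffic-driven species do carry a weekly cycle; leaving it off means
  the weekly cycle survives normalization and is averaged out at the
  monthly aggregation step.
* Normalization is done daily and aggregated to months by mean. Fitting
  monthly directly would leave too few rows for a forest.
* The per-date Monte-Carlo SD measures resampling spread only.
  Refit-level spread (forest seed sensitivity) is exposed separately by
  `normalization_uncertainty()`, which refits with distinct seeds and
  returns a min/max/sd envelope.

## Trend and baseline

Trends are OLS on days-elapsed, reported per decade with the exact
conversion 3652.5 days/decade. The observed-concentration trend is fit on
weekly means, the normalized trend on monthly means; both granularities
are parameters. `detrend()` returns both the signed anomaly and a
recentered variant (anomaly + whole-record mean), because some downstream
consumers need level inputs. Monthly baselines use exclusively the
baseline-flagged periods (2018–2019 by default).

The pipeline's default feeds the *normalized level series* (not the
detrended one) into attribution. Detrending first was considered and
rejected: the long-run decline lives mostly in the factory component, and
removing it before attribution leaves the sulfate tracer with no signal to
attribute, collapsing the factory split. A `detrend_before_attribution`
toggle preserves the alternative.

## Source attribution

`fit_attribution_model()` learns `g(NO3_norm, SO4_norm) -> BC_norm`
(nitrate traces transport NOx, sulfate traces industrial SO2; the mapping
is an argument, not hard-coded). `attribute_sources()` uses two-sided
counterfactual differences with the references `r_no3`, `r_so4` at the
5th percentile of each tracer: real tracer records never reach zero, and
querying a forest at zero would be severe extrapolation. The
interaction mass left between the two one-sided differences is allocated
proportionally to their absolute sizes (equally when both vanish), making

    bc_transport + bc_factory + floor = prediction

hold to machine precision on every row before clipping at zero (clipped
mass is logged, never silently dropped). The floor `g(r_no3, r_so4)` is
reported as its own term rather than forced into either source. The
attribution literature the design follows does not pin one algorithm; the
counterfactual-difference scheme was chosen because it satisfies the
additivity identity exactly and is reproducible; an exact tree-path
attribution could stand behind the same interface. Fit diagnostics (R²,
RMSE, best-fit slope) are computed on out-of-bag predictions — in-sample
forest predictions would overstate the fit quality badly enough to make
even a shuffled target look correlated.

## Transport statistics

`day_of_week_stats()` reproduces the published daily-variation table under
two deliberately verified conventions: the **population** (n-denominator)
standard deviation, and **round-half-away-from-zero** at two decimals.
Both were confirmed against the printed rows before being frozen (the
printed Thursday mean 1.63 distinguishes half-away from banker's
rounding; the printed Monday mean 1.02 is not reproducible from its own
printed weekly values and is excluded from exact checks). The
workday/weekend comparison is a two-sided Welch test; two equal constant
groups return t = 0, p = 1 by convention since the statistic is undefined.

`percent_change()` compares outbreak months to matched-calendar-month
baselines (mean over baseline years), so seasonality cancels; the measure
is scale-invariant. `segment_regression()` fits OLS of monthly `BC_Private`
on monthly public-transport volume strictly within each named regime;
ambiguous months (January 2020 in the motivating study: reported outbreaks
elsewhere, none yet locally) can be reassigned or excluded via
`overrides` rather than by editing data.

## Epidemic response

`build_monthly_panel()` aggregates months as: meteorology means except
precipitation (summed — totals drive behaviour, the rest are state
variables), vacation-day share, maximum ordinal transmission/fatality
ranks (zero outside outbreaks), summed cases, mean `BC_Private`, monthly
volumes. The ordinal encoding ships exactly as printed in the motivating
study — including the anomaly that the third variant carries the same
(1, 3) pair as the first even though its transmissibility is described as
the highest; the encoding is configurable, and the default deliberately
does not "fix" it.

`fit_response_model()` defaults to a shallow extremely-randomized forest
(1000 trees, depth 3, one random split per candidate, minimum leaf 5).
Monthly panels have only a few dozen rows against a dozen features; an
unregularized forest chases idiosyncratic splits on uninformative
features, which shows up as spurious structure in partial-dependence
curves. The shallow randomized default keeps the strong epidemic signals
(the case-count and rank effects remain monotone and significant) while
suppressing that artifact. Partial-dependence grids use the `n_grid`
interior quantiles (probabilities k/(n_grid+1)) so the sweep stays
strictly inside the observed range.

Significance is by permutation: the observed statistic is the OOB
permutation importance of the feature; the null distribution comes from
refitting with the feature column itself permuted; the one-sided p is
`(1 + #{null >= observed}) / (1 + n_permutations)`. The motivating study
attaches p-values to a forest without naming a test; permutation
importance is the standard choice that respects the model class.

## The synthetic generator

`simulate_scenario()` emulates a six-year daily urban record
(2018–2023) with the structure the analysis assumes:

* Meteorology: seasonal sinusoid + AR(1) per variable (AR coefficient
  0.7), with dew point constructed as temperature minus a positive gap,
  and a slow configured increase in ventilation (BLH +18 %/decade, wind
  +6 %/decade) so the raw concentration trend is steeper than the
  emission trend — the wedge between the two printed trend values.
* Factory emissions decline linearly (0.66 fraction/decade from a 3.0
  µg m⁻³ level, calibrated so the scenario's emission trend sits near
  −1.8 µg m⁻³/decade); sulfate is co-emitted with gain 1.2.
* Transport emissions: level 2.0 µg m⁻³ times a ±20 % weekly cycle, plus
  a regime-dependent coupling to public-transport volume with slopes
  +0.03 (pre), −0.17 (pandemic era) and +0.03 (post) µg m⁻³ per million
  monthly passengers — the printed regression slopes become generator
  parameters. Nitrate is co-emitted with gain 1.5 and a winter-high
  partitioning factor.
* Transport volumes: a shared demand process (0.2 %/yr growth, ±7 %
  seasonal cycle, AR(1) noise) scaled per mode and suppressed inside
  outbreak windows by the printed percent decreases (metro 16/30/49 %,
  bus 30/37/66 %, taxi 47/48/49 %), by a 12 % residual during the
  pandemic era between windows (partial recovery), and to 92 %/58 %/90 %
  of baseline afterwards.
* Outbreak windows are month-aligned (Feb–May 2020, Jul–Aug 2021,
  Nov–Dec 2022) so that month-resolution percent changes measure the
  configured suppressions directly; epidemic pulses are Poisson around a
  log-normal shape with totals 93/235/2000 cases.
* Biomass spikes arrive ~10/yr, exponentially sized (mean 1 µg m⁻³),
  three times likelier on dry days — the coupling that lets weather
  normalization absorb them.
* Dispersion factor: `exp(-0.25 z_wind - 0.35 z_BLH)`; observation noise
  SD 0.3 µg m⁻³ per species; all series clipped at zero.
* One master seed fans out into named substreams (met, truth,
  observations, epidemic), so regenerating one table never shifts
  another's randomness.

What the generator does **not** emulate: spatial structure (no gridded
fields; the bounding-box reader is exercised on constructed grids),
epidemic transmission dynamics (cases are a forced pulse, not an SIR
model), measurement drift or gaps, and real policy timelines beyond the
default window boundaries. Passing tests therefore demonstrate that the
estimators recover known structure of this class — not that any real
city's numbers are reproduced, which would require the undeposited
observational inputs.

## Verification design and problem sizes

Tests use three-year no-outbreak scenarios for estimator unit checks and
the six-year default scenario for end-to-end recovery; normalization
tests use 50–100 meteorology resamples and the acceptance checks 100–200,
sizes at which the Monte-Carlo error is far below the tolerances probed.
Where a check compares an estimate against "truth", the truth is computed
from a noise-free twin of the same scenario (same seed, noise parameters
zeroed), so systematic features such as the within-window emission shifts
are part of the target rather than bias. Confidence-interval coverage is
asserted for the majority of three replicate seeds, since a single
nominal-95 % interval is expected to miss about once in twenty runs.
The two trend estimates carry a sampling SD near 0.3 µg m⁻³/decade across
scenario realizations — an honest property of six-year records with
realistic dispersion noise, worth remembering when comparing any single
run's numbers.

## Known limitations

* `BC_Transport` recovers the *variation* of true transport emissions
  well (monthly correlation ≥ 0.8 on the default scenario) but
  understates their level: counterfactual differences measure the part
  of the prediction the tracers move above the reference floor. Use it
  as a proxy series, not an absolute emission rate.
* Forest-based normalization attenuates trends near record ends (no
  extrapolation), slightly shrinking recovered slopes.
* The regime regression attributes all within-regime association to one
  slope; it is an associational summary, as are the partial-dependence
  curves — no causal identification is claimed.
* Monthly transport volumes use a 30-day month convention when converted
  from daily values, following the source's stated simplification.
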