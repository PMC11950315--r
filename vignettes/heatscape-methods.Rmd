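---
title: "Methods: heatwave indices, model ranking, and the composite heat-risk pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heatwave indices, model ranking, and the composite heat-risk pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatscape)
```

## The analysis in one paragraph

`heatscape` takes daily near-surface maximum (`tasmax`) and minimum
(`tasmin`) temperature series per city, model and emission scenario,
detects heatwave events as runs of at least three consecutive days strictly
above a fixed city-specific 95th-percentile threshold, summarizes them into
five annual indices, evaluates each climate model against a reference
dataset with a rank-points scheme, quantifies future changes as percentages
of each model's own baseline with regional multi-model medians, aggregates
everything into a composite heatwave index (CHI) per city, and multiplies
the CHI with normalized population quantities to obtain heat-risk indices
under different socioeconomic pathways. A seedable synthetic generator
supplies ensembles with the statistical structure the analysis assumes, so
every stage is exercised end to end without external data.

## Detection model and its assumptions

The exceedance threshold is the empirical quantile (default `q = 0.95`) of
*all* days of the baseline window pooled — no day-of-year windowing. Pooling
matches the single-threshold-per-city design: the threshold is a fixed
climatological benchmark computed once on 1985–2014 and reused unchanged for
2025–2054 and 2065–2094, which is what makes future exceedance frequencies
interpretable as change relative to historical norms. The quantile uses the
linear-interpolation convention between order statistics (R's default
type 7); the same convention is used everywhere a quantile appears
(ensemble IQRs, box statistics), so all quantile-based results are mutually
consistent.

Exceedance is strict (`>`, not `>=`): a day exactly at the threshold is not
a heatwave day. Events are the *maximal* runs of exceeding days of length
at least `min_event_days` (default 3) — a 10-day run is one event, never
two, and a 2-day run is no event at all. Detection runs on the continuous
multi-year series, so an event may straddle 31 December.

Year attribution is the one place the annual indices need a convention:

* `HWN` counts an event in the year its **first day** falls in;
* `HWTD`, `HWMT` and `HHT` attribute each **heatwave day to its own**
  calendar year;
* `HWLD` is the longest *within-year* consecutive stretch of heatwave days.

No day is double-counted and no event is split at detection time. A side
effect is that the intuitive equivalence "no events started this year ⟺ no
heatwave days this year" can fail in the rare case of an event beginning in
late December; the synthetic generator confines episodes to the warm season,
so the case does not arise in the shipped tests, but real winter-heatwave
data could exhibit it. `HWMT` and `HHT` are *missing* (`NA`), never zero,
in event-free years — averaging zeros into intensity statistics would pull
them toward meaningless values; period means over the intensity indices
therefore also record how many years contributed.

## Model evaluation

For each city, the absolute deviation of each model's period-mean index from
the reference dataset's is computed, per diurnal dataset — ten slots per
city when both daytime and nighttime indices are available. When both are
supplied the comprehensive rank averages over all ten; the output records
how many slots contributed, and an index whose deviation is missing on
either side (an event-free intensity mean) is dropped from that model's
average with the divisor reduced. Per-index ranks use average ranks for
ties; the averaged rank is converted to a strict ordinal 1..n ordering with
ties broken by model id, because the points scheme (rank 1 of *n* earns
*n* points, down to 1) must hand out integer totals for the half-maximum
arithmetic to be exact. Selection is strict: a model exactly at the
threshold is not selected.

Because each model's indices are computed against that model's *own*
baseline threshold, a purely additive model bias cancels out of the
frequency and duration indices and survives only in the intensity indices
(`HWMT`, `HHT`), which are absolute temperatures. Bias ordering is
therefore recoverable from the rankings, but with less statistical power
than if all ten slots carried the signal — the parameter-recovery test in
the suite measures exactly this.

`r_squared()` is the squared Pearson correlation with pairwise deletion of
missing values — not a regression through the origin — and reports an
undefined result (`NA`, with a warning) rather than 0 when either series
has zero variance.

## Change analysis

Percentage changes are `((future − baseline)/baseline) × 100` with the
baseline being the *same model's* 1985–2014 mean, never the reference
dataset's, so model bias does not masquerade as change. Intensity changes
are computed on Celsius values; the ratio is scale- but not unit-invariant,
and the Celsius convention is fixed throughout the package (Kelvin is
accepted only at ingest). A zero baseline (possible for `HWN` in cool
cities) flags the change as undefined rather than producing infinities.

Aggregation order: city values are averaged (unweighted) within each region
per model and year first; the multi-model median and 25th/75th percentiles
are then taken across models; trend lines (OLS slope and squared
correlation) are fitted to the resulting median series. Fitting the median
series rather than pooled model-years was a genuine design choice: the
median series is what the regional trajectories display, and its trend is
robust to a single outlying model.

## Composite heatwave index

Within one period, scenario, model and diurnal dataset, each of the five
indices is min-max normalized across cities; the five normalized metrics
are averaged per dataset; day and night composites are averaged; and the
combined value is min-max re-normalized across cities. The normalization
scope follows the displayed per-period, per-dataset equations rather than a
global normalization across all models and periods: the CHI is a relative
ranking of cities within one analysis slice, and cross-period comparisons
are carried by the indices and percentage changes, not by the CHI itself.

Two degenerate rules are documented rather than implicit: a metric with no
spread across cities maps every city to 0 (a spreadless metric should not
raise anyone's hazard, and 0 keeps the composite's lower bound exact), and
a missing intensity component imputes 0 *after* normalization (an
event-free city carries the least possible intensity burden). The ensemble
CHI is computed per model first, then the per-city median across the
selected models is taken and re-normalized across cities, so the ensemble
product obeys the same [0, 1] span contract as each per-model CHI; the
hottest city scores exactly 1 and the coolest exactly 0 whenever the
inputs are non-degenerate.

## Risk overlay

Populations and signed population changes relative to 2020 are min-max
normalized *within one (SSP, horizon) slice* — the comparison the risk
heatmaps make is between cities under one scenario, not across scenarios.
The most-declining city maps to 0 on the change scale like any other value.
The two risk products are plain elementwise multiplications, so
`risk ≤ min(CHI, pop_norm)` always, and a city at the slice's population
minimum has zero absolute risk by construction. Which climate scenario
pairs with which SSP population pathway is an argument (`run_all` produces
both emission scenarios against all five SSPs, 2050 paired with the
near-future CHI and 2090 with the far-future CHI), never a hard-coded
pairing.

## Coastal classification

The city's representative point is classified coastal when its great-circle
distance to the coastline polyline is at most `buffer_km` (default 10 km,
boundary inclusive). Segments are treated as geodesic chords: the distance
to a segment is the cross-track distance where the perpendicular foot falls
inside the segment, otherwise the distance to the nearer endpoint, on a
sphere of radius 6371 km. At 10-km scale this is equivalent to a planar GIS
buffer while remaining projection-free. Coast groups (West / South /
East-North) come from the city table — they are descriptive labels, not
derivable geometry. Box statistics use type-7 quartiles with Tukey 1.5·IQR
whiskers and explicit outlier lists.

## The synthetic generator

`generate_truth()` draws, per city and scenario,

```
T(d) = mu + amp * cos(2*pi*(doy - peak)/365) + rate * (year - anchor) + episode(d) + eps(d)
```

with `eps` an AR(1) process (`phi = 0.7`, stationary sd `sigma = 2` °C by
default — typical midlatitude summer day-to-day variability), warm-season
heat-dome episodes as additive block shifts (Poisson 1.5 per season,
3 + Poisson(3) days long, uniform 2–6 °C amplitude) so that multi-day
exceedance runs actually occur, and `tasmin = tasmax − 10 °C + noise`,
clipped so `tasmax ≥ tasmin`. Warming rates default to 0.1 (historical),
0.3 (SSP2-4.5) and 0.6 (SSP5-8.5) °C/decade — bracketing the moderate and
fossil-fueled scenario families. The trend is anchored at a fixed
`anchor_year` (1985, the baseline start) rather than at each window's own
start: scenario warming accumulates continuously from the baseline era, so
a far-future window is warmer than the baseline by the decades elapsed, not
merely by its internal trend. Models are the shared truth plus an additive
bias and extra independent noise; the reference is the truth plus small
observation noise. Population trajectories multiply a 2020 base by per-SSP
factors for 2050 and 2090 (SSP3 declines by 2090) with optional lognormal
jitter.

Everything is driven by R's Mersenne-Twister generator; each series derives
its own sub-seed deterministically from the spec seed and the series'
identity, so any single series is reproducible without generating the rest
of the ensemble, and a fixed seed gives bit-identical ensembles.

What the generator does *not* emulate — and what passing tests therefore do
not demonstrate about real data: humidity and its heat-stress metrics,
spatial correlation between cities, non-stationary variance, urban heat
island structure within a city, model drift, or realistic coastline
geometry. The generator's job is to give the detection, ranking and
normalization machinery inputs whose ground truth is known, not to simulate
climate.

## Numerical choices and degenerate inputs

* Quantiles: type 7 (linear interpolation) everywhere.
* Exceedance: strict inequality; equality at the threshold is not an event
  day.
* Tie-breaks: model ids (ranking ordinals), city ids (top-city selection
  and hotspot ordering) — all documented, all ascending.
* Two calendars, proleptic standard and 365-day no-leap, never mixed within
  a series; the synthetic generator uses no-leap, matching CMIP6 model
  output and removing leap-day branching.
* Missing values: allowed only in reference series (pairwise deletion in
  comparisons); model series must be complete, and gaps in the daily
  calendar are rejected at ingest naming the first offending date.
* `netcdf_cf` is part of the reader interface but this build supports the
  `csv_long` dialect; NetCDF exports should be converted to the long CSV
  format.

## Problem sizes in the shipped tests

The suite exercises the pipeline at 10 cities × 5 models with the full
30-year baseline/near/far windows for the end-to-end determinism checks,
10 cities × 5 models × 20 replicate seeds for bias-order recovery, 50 seeds
of single-city 30-year series for trend recovery, and 1000 random 60-day
series against an exhaustive run-enumeration oracle for detection — sizes
chosen so the whole suite runs in a few minutes while every statistical
check retains enough data to be meaningful.

## Known limitations

Temperature-only hazard (no humidity or wet-bulb metrics); city points, not
polygons, for coastal classification; unweighted regional averages; the CHI
is ordinal within a slice, not comparable across periods; and the model
ranking's power to distinguish additive biases rests on the intensity
indices alone, as discussed above.
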