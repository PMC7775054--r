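---
title: "Model description and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model description and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenorisk)
```

`phenorisk` couples two process models driven entirely by daily minimum
and maximum temperature: a cohort-based degree-day phenology simulator
and a cold/heat stress accumulation model of climatic suitability. This
vignette describes both models, their assumptions, the parameters that
matter, the numerical choices made where behavior was genuinely open,
and what the synthetic-weather tests do and do not demonstrate.

## The phenology model

Development is linear in temperature between a lower (LDT) and upper
(UDT) developmental threshold, measured in degree-days Celsius (DDC).
Two daily calculators are provided, selected by the species parameter
`calctype`:

* **average** — the simple average with a horizontal cutoff: the daily
  mean temperature is clamped to `[LDT, UDT]` before subtracting the
  LDT. Cheap, and exact when the whole day stays inside the thresholds.
* **triangle** — the single triangle method with upper threshold: the
  day is modeled as a triangular excursion from Tmin to Tmax and back
  over 24 h, and the degree-days are the mean of that trajectory
  clipped to `[LDT, UDT]`, minus the LDT. The area above the UDT is cut
  off horizontally, not reflected. The closed form is verified in the
  test suite against a 1-minute numerical integration of the clipped
  trajectory on 10,000 random `(Tmin, Tmax, LDT, UDT)` tuples at an
  absolute tolerance of 0.01 DDC.

A degenerate day with `Tmin == Tmax` uses the constant-temperature
limit of the formula (continuity). Days with missing temperature
propagate missing values rather than zero, so absent weather can never
masquerade as a cold day; the engine freezes the simulation state on
such days and counts them per cell.

### Life cycle and cohorts

The simulated life cycle is egg → larva → pupa → adult → egg, with a
separately parameterized overwintering stage of one of those four
types. Simulation starts on a fixed calendar date (typically January 1)
with the whole population in the overwintering stage, generation 0. The
overwintering requirement is cohort-specific: the emergence
distribution — mean, variance, low and high bound, and shape (normal or
lognormal) in DDC — is discretized into `n` equal-width bins over
`[xdist1, xdist2]`; each cohort sits at its bin midpoint and carries
the truncated distribution's probability mass in that bin, renormalized
to sum to one. The discretization rule (midpoint value, exact bin mass)
is the simplest scheme that reproduces a small set of cohorts
approximating a normal distribution; with `n = 1` the single cohort
sits at the mean with weight 1. A degenerate distribution
(`distro_var = 0`) is allowed only with one cohort. For the lognormal
shape, the variate shifted by `xdist1` is lognormal with the stated
(natural-scale) mean and variance, converted internally to log-scale
parameters; this choice keeps the five distribution parameters
interpretable in DDC whatever the shape.

Each day the active stage's degree-days are added to a within-stage
accumulator. When the requirement (the cohort's own value for
overwintering, the stage duration otherwise) is reached, the insect
moves to the next stage and the excess degree-days carry into the new
stage's accumulator, so no development is lost on transition days. Two
deliberate restrictions apply:

* **At most one transition per calendar day.** Daily data cannot
  resolve sub-day multi-stage progress; without this rule one very hot
  day could skip a short stage entirely.
* **Threshold mixing.** When stages have different thresholds the
  excess is carried as-is; degree-days accumulated against one
  threshold are then spent against another. The two shipped species use
  common thresholds, where the scales are identical; for
  stage-specific thresholds this is a documented approximation.

The generation counter increments at every entry into the egg stage —
ordinary oviposition by adults, and emergence of an overwintering adult
(its first act is egg laying after the pre-oviposition requirement is
folded into the overwintering duration).

### Phenological events

Each non-overwintering stage has one within-stage degree-day milestone
(`event_dd`, constrained to `[0, stage_dd]`); the first day on which
the within-stage accumulator reaches it is recorded per generation, for
generations 0 to `max_event_generations - 1` (default 4). Later
generations are tracked for voltinism only. The overwintering stage's
event is emergence itself — the day the cohort completes its
overwintering requirement — since that date is what surveillance start
dates are planned around, and the milestone varies by cohort rather
than being a fixed within-stage constant. Event tables are finalized
only after the last simulated day.

Across cohorts, the earliest and the average event day are reported.
The average is weighted by cohort population fraction by default
(`weighted = FALSE` gives the plain mean) and rounded to the nearest
day. Stage/generation composition maps are produced for the middle
cohort (`ceiling(n/2)`), which under a roughly symmetric emergence
distribution represents the largest population share; the population
composition itself (fractions per generation and stage, summing to 1)
uses all cohorts.

## The climatic suitability model

Daily cold stress units are `max(0, threshold_cold - Tmin)`; heat
stress units are `max(0, Tmax - threshold_heat)`. One threshold pair
applies to all life stages — the thresholds of the stage most exposed
to winter cold and summer heat, respectively — and units accumulate
linearly across the entire run, never resetting, with consecutive days
weighted no higher than scattered ones. Accumulations are compared to a
moderate limit (`max1`, most individuals die) and a severe limit
(`max2`, all individuals die): a cell is excluded at a level only when
its accumulation *strictly exceeds* the limit, so boundary equality
remains unexcluded. Because `max1 < max2` is enforced, severe exclusion
always implies the moderate threshold was passed, and a cell's class
never de-escalates over time.

Every phenology output except accumulated degree-days is also produced
in two masked variants — severe exclusion only, and severe plus
moderate — with sentinel codes `-1` (moderate) and `-2` (severe) in
place of the phenology value. Per-day layers use that day's exclusion
state; end-of-run maps (voltinism, event days) use the final day's.
For display, accumulated stress can be rescaled linearly so the grid
maximum maps to 1000.

## Parameters

All temperatures are degrees C internally. Parameter files may declare
`units: F`, in which case *threshold* temperatures are rounded to the
nearest integer Fahrenheit before conversion (the long-standing
convention for communicating degree-day models in the United States)
while degree-day quantities scale by 5/9 exactly; Celsius input is
never rounded. Gridded weather data are converted exactly, without
rounding, whatever the unit.

The key knobs and their defaults:

| parameter | unit | default | note |
|---|---|---|---|
| `n_cohorts` | — | 7 | enough to resolve the emergence spread without noticeable discretization error |
| `sample_every` | days | 30 | output sampling; the final day is always included because event maps need the full period |
| `max_event_generations` | — | 4 | event bookkeeping horizon; voltinism is unlimited |
| `calctype` | — | triangle | closer to the sine method than the simple average |
| `weighted` | — | TRUE | cohort-weighted average event dates |

The sampled-day grid is `1, 1 + k, 1 + 2k, ...` plus the final day even
when the period length is not a multiple of `k`; a 365-day run sampled
every 30 days yields 14 layers (days 1, 31, ..., 361, 365).

## The synthetic weather generator

`synth_spec()`/`generate_weather()` produce a fully deterministic (per
seed) daily Tmin/Tmax cube with three ingredients: a linear north–south
gradient (`lat_gradient` per row, row 1 = north), a sinusoidal seasonal
cycle peaking on day 196 (mid-July, northern hemisphere), and a fixed
diurnal range around the daily mean, plus optional i.i.d. Gaussian
noise. The daily mean in row *r* counted from the south edge is

```
base_mean - lat_gradient * r - seasonal_amplitude * (1 - cos(2*pi*(d - 196)/365))
```

so `base_mean` is the south-edge mean on the warmest day and the
seasonal swing is twice the amplitude. The defaults (20 × 20 cells,
365 days, `base_mean` 35 °C, gradient 1.5 °C/row, amplitude 12 °C,
diurnal range 10 °C) emulate a mid-latitude continental domain whose
south edge reaches desert-summer maxima near 40 °C and whose north edge
has winters well below freezing — the combination under which both a
northern cold-exclusion band and a southern heat-exclusion band appear
for the shipped species, voltinism increases southward, and every
closed-form engine test can be driven by the constant (gradient- and
amplitude-free) special case.

What the generator does **not** emulate: spatial covariance and
topography of real temperature products, day-to-day weather
autocorrelation, asymmetric seasons, or diurnal-range variation.
Passing the gradient-geography tests therefore shows that the model
produces the right *qualitative* spatial structure under a monotone
forcing, not that it reproduces any real region's fields.

For historical monthly climate normals, `monthly_to_daily()` downscales
12 monthly means to a smooth daily series: linear interpolation between
month-midpoint anchors (wrapping December–January cyclically), then an
iterative correction that adds a smooth midpoint-interpolated residual
curve until every realized monthly mean matches its input within
0.01 °C (cap 100 iterations, with the residual reported on failure).
The contract is mean preservation, not a particular smoother; the
property suite checks it on random monthly vectors.

## Gridded pipeline, tiling, and determinism

The grid engine advances all cells of all cohorts in lock-step through
the daily loop, using exactly the same state-update code as the
point-wise API (`run_cohort()` is a one-cell grid), so a grid cell and
a point run on that cell's series cannot drift apart. Accumulated
degree-day maps follow the first cohort under larval thresholds, which
is representative for all cohorts and stages when thresholds are
common.

Because no cell interacts with any other, a run may be split into any
number of rectangular tiles and mosaicked: `tile_and_mosaic()` is
required — and tested — to be bit-identical to the untiled run for
even, uneven, and trivial tilings. Outputs are deterministic given the
configuration; the only randomness anywhere is the synthetic-weather
seed. GeoTIFF files are written with a fixed byte layout, so identical
runs produce byte-identical files (verified by checksum in the tests).

Rasters are written as uncompressed little-endian GeoTIFFs (float32, or
int32 for class/code/day layers), one band per sampled day with dates
as band names, geographic WGS 84 referencing, nodata `-9999`, north-up,
cell-center registration half a cell inside the tie-point corner. The
codec is deliberately minimal and is cross-checked in the tests against
an independent TIFF reader. Event-day maps are rendered with month-day
calendar labels (leap years use the actual calendar); exclusion
classes use the categorical labels "excl.-moderate" and "excl.-severe".

## Verification sizes

The shipped test and acceptance suites run at desk scale, chosen so the
full suite completes in well under a minute: closed-form phenology
checks on 365-day constant-temperature series; the triangle oracle on
10,000 random tuples; spatial contracts (tiling bit-identity,
grid-equals-point, gradient geography) on a 20 × 20 × 365 cube with
seven cohorts; interpolation properties on 100 random monthly vectors.
Continental-scale grids differ only in cell count — per-cell work is
identical — so these sizes exercise every code path the large runs use.

## Known limitations

* Entirely temperature-driven: no moisture or dry/wet stress, no
  photoperiod, diapause triggers, or migration. Predictions for
  moisture-sensitive species in arid or very wet regions should be
  read with caution.
* Linear degree-day development without distributed delay: cohort
  overlap does not widen across generations, so event maps are most
  reliable for the first few generations.
* One phenological event per stage per generation, for the first
  `max_event_generations` generations only.
* The carry-over approximation across stages with different thresholds
  described above.
* The climatic suitability component classifies exclusion only; it
  does not produce a graded suitability index.
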