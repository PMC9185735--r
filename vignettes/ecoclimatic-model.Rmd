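---
title: "The ecoclim ecoclimatic suitability model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ecoclim ecoclimatic suitability model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoclim)
```

## The model

`ecoclim` implements a compare-locations ecoclimatic niche model of the
CLIMEX family. For each location (or grid cell) it takes long-term
monthly climate normals — maximum and minimum temperature, precipitation,
and relative humidity at 09:00 and 15:00 — and produces an annual
**Ecoclimatic Index** (EI, 0–100) summarising how suitable that climate is
for the persistence of a warm-adapted soil organism. The shipped
parameter set describes the entomopathogenic nematode *Heterorhabditis
indica*, whose infective juveniles live in the soil water film: its
population growth responds to soil temperature and soil moisture, and its
survival is cut down by accumulating cold, heat, dry and wet stress.

The pipeline for one location is:

1. **Weekly interpolation.** Monthly normals are interpolated
   piecewise-linearly between successive month midpoints with annual
   wrap-around, onto 52 equal weeks of 365.25/52 ≈ 7.024 days; month
   midpoints sit at the cumulative-day centres of a 365.25-day calendar.
   Precipitation is first converted to a weekly rate and afterwards
   rescaled so the 52 weekly values sum exactly to the annual total (the
   sampling of a piecewise-linear rate at 52 points conserves mass only
   approximately; the rescale makes it exact). Weekly mean temperature is
   `(tmin + tmax)/2` and weekly humidity the mean of the two observation
   times.

2. **Soil moisture.** A single-layer weekly bucket, expressed as a
   fraction of field capacity `SM` (`SM = 1` is field capacity; values
   above 1 represent waterlogging, up to a ceiling `sm_cap`):

   `SM_w = clamp(SM_{w-1} + (rain_w - evap_w - drain_w) / capacity, 0, sm_cap)`

   with evaporative demand `k_e · max(tmean_w, 0) · (1 - RH_w/100)` mm,
   actual evapotranspiration equal to demand scaled by `min(SM, 1)`
   (moisture-limited), and drainage `k_d · capacity · max(SM - 1, 0)` mm
   of the water standing above field capacity. The annual cycle is
   iterated to a periodic fixed point, so results do not depend on the
   initial moisture.

3. **Weekly growth indices.** A trapezoidal temperature index TI over
   `(DV0, DV1, DV2, DV3)` applied to weekly mean temperature and a
   trapezoidal moisture index MI over `(SM0, SM1, SM2, SM3)` applied to
   `SM`; the weekly growth index is `GI_w = TI_w × MI_w` and the annual
   growth index `GI_A = 100 × mean(GI_w)`.

4. **Stress accumulation.** Four stresses accumulate weekly beyond their
   thresholds: cold uses the weekly *minimum* temperature below TTCS,
   heat the weekly mean above TTHS, dry the soil moisture below SMDS and
   wet the soil moisture above SMWS. Weekly stress is
   `rate × exceedance × run length`, where the run length is the number
   of successive weeks the stress has been active; the annual total is
   the sum over weeks.

5. **Combination.** `EI = GI_A × Π max(0, 1 - min(S, 1))` over the four
   stress totals; any stress total reaching 1 is lethal. EI classes:
   0 unsuitable, (0, 10) marginal, [10, 20) suitable, ≥ 20 very
   suitable. Regional area summaries use a separate "climatically
   suitable" cutoff of EI ≥ 1.

## Parameters that matter

The shipped *H. indica* set
(`inst/extdata/heterorhabditis_indica.params`):

| block | values | meaning |
|---|---|---|
| temperature (°C) | DV0 = 18, DV1 = 25, DV2 = 30, DV3 = 33 | growth support and optimum plateau, on weekly mean temperature |
| moisture (fraction of field capacity) | SM0 = 0.08, SM1 = 0.1, SM2 = 0.7, SM3 = 1.7 | growth support and optimum plateau, on weekly soil moisture |
| cold stress | TTCS = 11 °C, THCS = 0.0002 | threshold on weekly minimum; rate per °C·week |
| heat stress | TTHS = 36 °C, THHS = 0.0003 | threshold on weekly mean; rate per °C·week |
| dry stress | SMDS = 0.08, HDS = 0.001 | threshold and rate on soil-moisture fraction |
| wet stress | SMWS = 1.7, HWS = 0.003 | threshold and rate on soil-moisture fraction |

Growth is zero *at* the support endpoints (DV0, DV3, SM0, SM3): the
trapezoid's support is treated as an open interval, which is the
conservative reading when lethal/stress thresholds sit exactly at the
endpoints (SMDS = SM0 and SMWS = SM3 here). A parameter set with
`DV1 = DV2` has a single-point optimum; zero-width ramps degenerate to
steps.

Two deliberate classification choices: EI exactly 20 is classed very
suitable (the class boundaries are ≥ 10 and ≥ 20), and the limiting
factor reported per cell is the *largest* accumulated stress (the
quantity a per-stress map displays), which need not have reached the
lethal 1.0 — a desert cell can be unsuitable because MI = 0 year-round
while its largest stress total is only ~0.1.

## The hydrology stand-in

The bucket model is this package's own construction; closed commercial
implementations of this model family do not publish their internal
hydrology, so absolute soil-moisture values (and hence MI, dry and wet
stress) are not expected to match any other software cell-for-cell. The
three constants were fixed from first principles, not fitted:

* `k_e = 7` mm·°C⁻¹·week⁻¹ — makes annual evaporative demand in the warm
  tropics (mean 26 °C, RH ~82%) about 1500 mm, the textbook magnitude of
  tropical potential evapotranspiration. A demand coefficient much
  smaller than this makes every wet climate saturate permanently, which
  would misclassify rainforests as waterlogged deserts of growth.
* `capacity = 100` mm — a common order for the plant-available water of
  one soil layer.
* `k_d = 0.2` week⁻¹ — drainage of the water standing above field
  capacity. Without a drainage term a bucket whose inflow exceeds demand
  in every week has its fixed point pinned at the ceiling `sm_cap`;
  with it, persistent surplus settles at
  `SM = 1 + surplus/(capacity × k_d)`, so only genuinely waterlogged
  climates approach the wet-stress threshold of 1.7.
* `sm_cap = 2.5` — ceiling on waterlogging, chosen so the wet-stress
  threshold 1.7 is reachable with headroom.

Actual evapotranspiration scales with `min(SM, 1)` so that a drying soil
loses water ever more slowly — the standard single-bucket closure — and
the recursion then has a unique attracting periodic cycle for any
climate with nonzero demand or rain.

## Stress run lengths are cyclic

Climate normals describe a periodic year. A cold spell that spans the
week-52 → week-1 boundary is one spell, so run lengths are counted
cyclically; otherwise a mid-winter artefact of the calendar would split
a northern winter into two short runs and roughly halve the accumulated
cold stress of exactly the climates the cold-stress mechanism exists to
exclude. If all 52 weeks are stressed the run is counted 1..52 from
week 1. Linear accumulation (no cap or compounding within the year) is
used; the annual totals are capped at 1 only when combined into EI.

With the shipped rates, dry stress is bounded above by
`HDS × SMDS × Σ(1..52) ≈ 0.11` (the exceedance cannot exceed SMDS), so
deserts are excluded through MI = 0 rather than through lethal dry
stress — dry stress still dominates their stress profile and is
reported as the limiting factor.

## The synthetic climate generator

Six Köppen–Geiger archetypes (Af, Aw, BWh, Csa, Cfb, Dfb) are shipped as
a parameter table (`koppen_archetypes()`): annual mean temperature,
seasonal amplitude, diurnal range, annual rainfall, rainfall seasonality
shape and baseline humidity. `generate_archetype_normals()` builds a
sinusoidal monthly temperature cycle phased by hemisphere, distributes
rainfall by the seasonality shape, and nudges humidity up in the rainy
season; `generate_grid()` tiles archetypes into a lattice with optional
seeded Gaussian jitter; `generate_occurrences()` samples presence-only
records from suitable cells, with a configurable miss rate emulating the
occasional record that climate alone cannot explain (favourable
microhabitats such as irrigated orchards in deserts).

The archetype values are textbook climatologies of each class, fixed
once as calibration fixtures for the test-bed. Under the shipped
parameters and default hydrology they reproduce the expected
biogeography: wet tropics very suitable (EI(Af) ≈ 41, EI(Aw) ≈ 82), hot
desert excluded with dry/heat stress dominant, Mediterranean marginal
(EI(Csa) ≈ 6), oceanic and cold continental excluded by cold
(CS(Dfb) ≈ 2.25 ≥ 1).

What the generator does *not* emulate: spatial autocorrelation beyond
block structure, interannual variability, orography, coastlines,
observational error structure of real normals, and real coordinates of
any station. Passing tests on synthetic grids therefore demonstrate the
*mechanics* of the model — interpolation, hydrology, stress arithmetic,
area accounting, verification plumbing — not predictive skill on real
climate surfaces, which additionally depends on the input data and on
the hydrology stand-in above.

## Numerical choices

* Soil-moisture fixed point: iterated to a per-year sup-norm change
  below 1e-9 (initialisation-independence then holds well below the
  1e-6 documented guarantee); convergence is judged per cell and
  converged cells are frozen, so a cell's trajectory is identical
  whether run alone or inside a grid — the vectorized grid engine and a
  scalar per-cell loop agree to ~1e-12, limited only by BLAS summation
  order in the interpolation.
* A configurable iteration ceiling (500 years) guards the degenerate
  zero-rain/zero-demand case, which has no unique cycle and errors
  rather than returning an initialisation-dependent answer.
* Cell areas for regional summaries are exact spherical band areas
  `R² Δλ (sin φ_n − sin φ_s)`; point-in-cell lookup uses cell-centre
  registration with half-open intervals, west/south edges inclusive.
* Raster files are multiband 32-bit float TIFF with values packed
  linearly into the [0, 1] sample range; per-band ranges, band names and
  the georeferencing travel in plain-text sidecars. Round trips are
  exact to float32 resolution (~1e-7 relative).
* Test and acceptance problem sizes — 5×5 grids for the
  vectorized-vs-scalar oracle, 100 random climates for monotonicity,
  12×12-cell blocks for occurrence sampling — were chosen as the
  smallest sizes at which each property is meaningfully exercised; the
  whole suite runs in well under a minute.

## Known limitations

* The hydrology is a stated stand-in (see above); only the *relative*
  geography of moisture indices and moisture stresses is meaningful.
* Stress interaction terms (cold-wet, hot-dry, …) are not modelled; the
  shipped parameter set defines none.
* No degree-day phenology, diapause, irrigation scenarios or
  climate-change modes; the model evaluates one historical climate per
  location independently ("compare locations").
* Grid I/O is CSV plus the TIFF-with-sidecars format; NetCDF is not
  read or written.
* The classifier's microhabitat blindness is inherited from the model
  family: a coarse-cell climate model cannot see irrigated orchards,
  shaded gullies or soil-type refugia.
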