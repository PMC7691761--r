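---
title: "Delineating and evaluating technology extrapolation domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating and evaluating technology extrapolation domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tedzone)
```

## The problem

Agronomic field trials are expensive, and their results only transfer to land
where climate and soil would produce a comparable crop response. A
*technology extrapolation domain* (TED) is a zone with a unique combination
of climate-zone class and root-zone plant-available water holding capacity
(PAWHC) class, within which rainfed crop yields, their inter-annual
stability, and hence the response to a management technology are expected to
be similar. Given a TED map, three practical questions follow, and this
package answers all of them:

1. **Coverage.** How many zones must a trial network touch to represent a
   target share of a crop's harvested area?
2. **Evaluation.** Does the zonation actually separate regions that differ
   in yield level and yield stability?
3. **Transfer.** Where else in the world does the same zone occur, and how
   do cropping systems practised there compare economically?

## The zonation model

Four per-cell biophysical factors define a TED:

* **Growing degree-days (GDD)**, `sum(max(0, min(T, cap) - T_base))` over a
  calendar year, averaged over years. This proxies the length of time crop
  growth is not limited by cold. The base temperature defaults to 0 degC
  with no cap; both are configurable (`compute_gdd()`), since published
  zonations differ in these constants.
* **Aridity index**, annual precipitation over annual reference
  evapotranspiration, averaged over per-year ratios. It captures the degree
  of water limitation: lower is drier. Reference ET defaults to
  Hargreaves-Samani (`compute_pet_hargreaves()`) because it needs only
  temperature and latitude; a supplied PET band always overrides it.
  Penman-Monteith is deliberately out of scope: it requires humidity, wind
  and radiation inputs outside this data model.
* **Temperature seasonality**, the *population* standard deviation of the
  12 mean monthly temperatures, averaged over years. It separates temperate
  from tropical climates. The population (not sample) SD is a fixed,
  documented convention: the 12 months are the complete population of the
  year, not a sample from it.
* **PAWHC class**, `floor(pawhc / interval)` with the class interval the
  resolution knob of the whole framework: 50 mm gives the *moderate* and
  25 mm the *high* resolution scheme. A 260 mm soil is class 5 at 50 mm
  (the 250-300 mm band) and class 10 at 25 mm (250-275 mm).

Multi-year aggregation is always the arithmetic mean of per-year index
values, never the index of mean weather; the distinction matters for the
aridity ratio. All binning is half-open and lower-inclusive — a value equal
to a boundary belongs to the upper class — one stated convention rather
than four silent ones. `NA` (NoData) in any input propagates to the TED
raster and never reaches class statistics.

The default climate-class boundaries (`ted_scheme()`: 10 GDD classes every
1000 degC-day, 10 aridity classes every 0.2, seasonality boundaries at 5
and 10 degC) are an editable configuration mirroring the coarse structure
of published climate zonations, not ground truth; any study region should
review them. TED codes render as `"CZ<g>.<a>.<s>-W<p>"` and pack
bijectively into one integer for raster storage.

## Coverage and placement

`crop_area_by_ted()` sums a harvested-area raster per zone;
`coverage_curve()` sorts zones from largest to smallest crop area (ties
broken lexicographically by code so results are deterministic) and
accumulates fractions of *total crop area* — cells without crop contribute
nothing to the denominator. Because each trial site is assumed to cover
exactly one whole zone, the curve is simultaneously the *efficiency
frontier*: `reallocate_max_coverage(n)` (the n largest zones) is provably
the best any n single-zone sites can do, and
`minimal_sites_for_coverage(target)` (the shortest prefix reaching the
target) is a minimum-cardinality solution. Both facts are nevertheless
tested against exhaustive subset search on small random tables rather than
taken on faith. The one-site-per-zone assumption ignores trial-loss risk;
placing replicates within a zone is a deliberate user decision, not a
package default.

## Evaluating the zonation against yield panels

Administrative units (counties) are attached to zones by the majority rule:
a unit joins the TED holding **strictly more than 50%** of its crop area
(cell-centre-in-polygon membership); an exact 50/50 split stays unassigned.
Yield panels are then summarised per zone:

* mean yield over unit-year records;
* inter-annual CV computed **per unit** over its years (sample SD / mean,
  in percent, requiring at least 3 years) and then averaged over the
  group's units. Pooling records before taking the CV would conflate
  spatial with temporal variance; the per-unit-then-average convention is a
  package choice, documented here because data sources rarely state theirs.

`variance_partition()` decomposes unit-year yields by sequential sums of
squares with the TED factor entered first, then the year main effect plus
the TED-by-year interaction as one combined term, then the residual. The
headline statistic is the TED share *excluding* the error term — the share
of explainable variance attributable to the zonation. Sequential ordering
matters in principle; the synthetic panels used in tests are balanced, which
makes the ordering immaterial there. `factor_r_squared()` reports the
coefficient of determination of unit-level means (and CVs) on all four
class factors entered together; a stepwise-selection variant was considered
and rejected — selection mechanics are routine statistics and add nothing
to evaluating the zonation itself.

## Analog transfer and cropping-system economics

`find_analog_teds()` intersects the code sets of two rasters delineated
under an identical scheme (a scheme mismatch is an error, not a silent
recode). Within a shared zone, `compare_systems()` evaluates cropping
systems supplied as per-year, per-crop yield/price/cost records: annual net
income is gross income minus variable and overhead costs, and risk is the
inter-annual CV of income under the same sample-SD convention as yields.
Crop growth simulation is out of scope by design — water-limited yields
produced by a crop model are *inputs* here; the package's contribution is
the zone matching and the income/risk accounting. `apply_sowing_rule()`
implements opportunistic double-cropping: a crop with a soil-water-at-sowing
series is only sown when that water is at or above a threshold (default
60 mm), and a skipped year sheds the crop's variable-cost share but not
overheads.

## What the synthetic generator emulates

Real inputs for this framework (gridded weather, soil and harvested-area
rasters, county yield panels) are large external products, so the package
ships a generator that plants exactly the structure the framework assumes:

* a north-south thermal gradient and a west-east moisture gradient, so the
  three indices vary smoothly in orthogonal directions (defaults:
  150 degC-day per 10 km row, 0.03 aridity index per column, spanning
  several classes of each over the default 200 x 200 km grid);
* blocky PAWHC drawn from 100-350 mm in 25 mm steps — patchy like soil
  maps, and fine enough that the 25 mm scheme genuinely refines the 50 mm
  scheme;
* crop area concentrated by a power-law weight, emulating the skewed
  harvested-area distribution that makes coverage curves strongly concave;
* yield panels generated as
  `base + 0.5 * pawhc_class + 0.4 * ai_class + lambda(unit) * year_effect +
  noise`, with the year effect drawn once and shared by all units
  (regionally correlated weather years) and `lambda` decreasing with PAWHC
  class, so mean yield rises and CV falls with water supply. The
  0.5 Mg/ha-per-class default encodes the rule of thumb that 25 mm of
  additional crop water supply buys about half a tonne of cereal yield in
  water-limited temperate systems.

Weather is generated monthly — a sinusoidal annual temperature cycle plus
region-wide monthly anomalies shared across cells — and resampled to daily
values by linear interpolation (temperature) or uniform spreading
(precipitation), on a 365-day calendar. The three indices only need monthly
fidelity, so a daily stochastic weather generator would add realism the
downstream computation cannot see. Solar geometry for PET uses the grid's
central latitude for every row: the fixture's thermal gradient is carried
entirely by temperature, and tying PET to per-row latitude would entangle
the two gradients (and make a zero-gradient grid spuriously heterogeneous).

What the generator does **not** emulate: real geography, spatially
correlated daily weather, irrigation, trends or autocorrelation in year
effects, non-additive climate-soil interactions, and measurement error in
reported yields. Passing tests therefore demonstrate that the algorithms
are correct and the statistical machinery recovers planted structure — not
that any particular real region satisfies the generative assumptions.

## Numerical choices and degenerate inputs

* Deterministic everywhere: all generator randomness flows from one
  explicit seed through a save/restore wrapper, so library calls never
  disturb the caller's RNG stream, and pipeline reruns are byte-identical.
* Coverage ties break lexicographically; cumulative fractions carry a
  1e-12 guard so floating-point never denies a target of exactly 1.0.
* Degenerate inputs fail loudly and early: empty or partial-year
  temperature series, non-positive PET, misaligned rasters (no implicit
  resampling — alignment is an explicit, separate decision), rasters
  without a CRS declaration, panels shorter than 3 years, single-level
  factors in the variance partition.
* A saturated or aliased R-squared design is reported with a flag rather
  than raised, since it is a legitimate (if uninformative) outcome on small
  regions.

## Problem sizes

Tests and the acceptance script run on grids of 10 x 10 to 20 x 20 cells
with 3-5 simulated years, panels of up to 200 units x 10 years with 20
Monte-Carlo replicates, and exhaustive subset search up to 12 zones (4096
subsets). These sizes are where every property being checked is already
fully expressed — zone recovery is exact at any size, and the Monte-Carlo
recovery tolerance (±0.05 on the planted variance share) is comfortably
met — while keeping the whole suite fast enough to run habitually.

## Known limitations

* Raster I/O is plain-text ASCII grid with a CRS sidecar; for large real
  rasters users will want to convert from their native formats first, and
  no reprojection or resampling is offered (by design: alignment must be
  explicit).
* The exact class boundaries used by published continental TED maps are not
  restated here; reproducing a published map requires configuring
  `ted_scheme()` from its source.
* The county majority rule uses cell-centre membership; slivers smaller
  than a cell are invisible to it.
* Income accounting is per-hectare and single-enterprise; whole-farm
  constraints (rotational labour, machinery, price risk) are out of scope.
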