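# tedzone

Agronomic field trials only extrapolate to land where climate and soil would
produce a comparable crop response. `tedzone` delineates **technology
extrapolation domains (TEDs)** — zones with a unique combination of
climate-zone class and binned root-zone plant-available water holding
capacity (PAWHC) — and provides the analyses that make such a zonation
useful to agronomists and research planners:

* **Climate indices** per grid cell, averaged over years: annual growing
  degree-days `GDD = Σ_days max(0, min(T, cap) − T_base)`, aridity index
  `AI = P / PET` (Hargreaves–Samani reference ET by default), and
  temperature seasonality (population SD of the 12 monthly means).
* **Zonation**: half-open lower-inclusive classification of the three
  indices plus `floor(PAWHC / interval)` classes at a 50 mm (moderate) or
  25 mm (high) resolution, intersected into per-cell codes `CZ<g>.<a>.<s>-W<p>`.
* **Coverage and trial placement**: crop-area coverage curves over zones,
  the efficiency frontier, and greedy (provably optimal) selection of the
  fewest zones reaching a target share of harvested area.
* **Evaluation**: county-to-zone assignment by the strict >50% crop-area
  majority rule, zone-level mean yield and inter-annual CV
  (sample SD / mean, per unit then averaged), variance partitioning of
  yield panels into TED vs year(+interaction) vs error, and all-factor R².
* **Analog transfer**: zone-code intersection across disjoint regions and
  income/risk comparison of cropping systems (net income = gross income −
  variable − overhead costs; opportunistic crops gated by a ≥ 60 mm
  soil-water-at-sowing rule).

A synthetic-data generator produces gridded weather with orthogonal
thermal/moisture gradients, blocky PAWHC, concentrated crop area, admin
units and yield panels whose mean rises and CV falls with water supply —
so the whole pipeline runs, and is tested, with no external downloads.
Rasters are read and written as plain-text ESRI ASCII grids with a CRS
sidecar; polygons and sites as GeoJSON; tables as CSV.

## Worked example

```r
library(tedzone)

cfg     <- fixture_config(seed = 42)          # 20 x 20 cells, 10 km, 5 years
weather <- generate_weather_grid(cfg)
indices <- compute_index_rasters(weather)
pawhc   <- generate_pawhc_raster(cfg)
region  <- generate_crop_area_and_units(cfg)

ted <- delineate_teds(indices, pawhc, ted_scheme(pawhc_interval = 50))
ted
#> <ted_raster> 39 distinct TEDs over 400 classified cells (PAWHC interval 50 mm)

curve <- coverage_curve(crop_area_by_ted(ted, region$crop_area))
head(curve, 3)
#>   rank   ted_code crop_area_ha cumulative_fraction
#> 1    1 CZ3.6.1-W5     67065.66          0.06706566
#> 2    2 CZ5.5.1-W2     66499.41          0.13356507
#> 3    3 CZ4.4.1-W6     66089.14          0.19965422
teds_for_coverage(curve, 0.5)
#> [1] 9
```

Nine of the 39 zones already hold half the region's crop area — the
diminishing-returns shape that makes strategic trial placement worthwhile.
Evaluating a simulated 10-year county yield panel against the zonation:

```r
panel <- generate_yield_panel(ted, region$units, yield_effect_spec(),
                              years = 10, seed = 42)
variance_partition(panel)$ted_share_excl_error
#> [1] 0.69
head(zone_summaries(panel, "pawhc_class"), 5)
#>   group n_units mean_yield cv_percent
#> 1     2      23       8.09       9.26
#> 2     3       6       8.07       8.65
#> 3     4      20       8.83       7.05
#> 4     5      43       9.62       6.04
#> 5     6       8      10.23       5.44
```

The zonation explains 69% of the explainable (non-error) variance in this
panel, and across PAWHC classes mean yield rises (8.1 → 10.2 Mg/ha) while
the inter-annual CV falls (9.3% → 5.4%) — better soils yield more and more
stably, which is exactly the structure a useful zonation must separate.

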