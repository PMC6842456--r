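# rhinomove

Mesoscale movement and recursion analysis for gappy megaherbivore GPS
telemetry.

Movement ecologists studying large, rarely collared herbivores — black
rhinoceros being the motivating case — face relocation data that are
irregular (1 fix/hour down to fewer than 3/day), gappy, and too sensitive
to publish. rhinomove implements a complete analysis of *recursion* (an
animal's repeated return to previously used places) on such data at three
nested scales, together with a seeded synthetic-trajectory generator so the
whole pipeline is testable and demonstrable without real coordinates.

The three scales, and the statistics at their core:

* **Diel displacement.** Fixes are standardised to four diel anchors —
  dawn 07:00, midday 13:00, dusk 19:00, midnight 01:00 local, each ±2.5 h,
  closest fix wins — and displacement between anchor slots 6/12/24 h apart
  is divided by the exact elapsed time, giving rates in m/h that are
  comparable despite irregular sampling. Rate distributions are compared by
  anchor/season/sex with pairwise Kolmogorov–Smirnov tests under Bonferroni
  correction; per-individual 24-h series are screened for periodicity with
  Fisher's exact g test, `g = max I_k / Σ I_k` with the exact short-series
  null `P(G>g) = Σ_j (−1)^{j−1} C(m,j)(1−jg)^{m−1}`.
* **Biweekly recursion on a 1 km² grid.** Trajectories are cut into the
  16-day compositing calendar of satellite greenness imagery (windows with
  ≥ 15 fix-days qualify). Per cell, in-cell fixes split into separate
  visits where gaps exceed a 12-h inter-visit gap (ivg), yielding **nsv**
  (number of separate visits) and **mlsv** (mean locations per visit).
  Cells join to contemporaneous NDVI summaries (pixel-centre rule), and
  `nsv ~ greenness` linear-vs-quadratic fits (AIC) characterise the
  hill-shaped preference for mid-range greenness.
* **Annual recursion and home range.** The same visit machinery at a 7-day
  ivg gives time-to-return distributions (end of one visit to start of the
  next, cells with ≥ 3 visits, waterhole cells excluded), per-individual
  range/revisitation metrics with Pearson correlations, k-LoCoH 90%
  utilization-distribution isopleths per 16-day window (k = ⌈√n⌉ by
  default; exact union-area computation), and a random-intercept model
  `log(area) ~ greenness + (1 | individual)` fit by REML.

All user-facing functions take plain data frames (one row per fix, per
cell, per interval) and return tibbles, so stages chain with the pipe;
fitted objects have `tidy()`/`glance()` methods and result types have
`autoplot()`/`plot_*()` companions.

## Worked example

```r
library(rhinomove)
library(dplyr)

# a seeded synthetic study: 6 animals, 64 days, patches at NDVI 0.25
sc <- generate_scenario(scenario_config(
  n_individuals = 6, n_days = 64, fix_dropout_prob = 0.15,
  patch_revisit_cycle = 4, patch_dwell = 1, n_patches = 6,
  dusk_water_bias = 0, rng_seed = 42))

tu <- biweekly_time_use(sc$trajectories)
tu
#> <biweekly_timeuse> 867 interval-cells over 18 qualifying intervals (ivg 12 h)
sprintf("mean nsv %.2f, mean mlsv %.2f", mean(tu$cells$nsv), mean(tu$cells$mlsv))
#> [1] "mean nsv 2.33, mean mlsv 2.22"

recursion_vs_ndvi(join_cells_greenness(tu, sc$rasters))
#> nsv ~ greenness model comparison (n = 867 cells)
#>   linear AIC 3385.4, quadratic AIC 3372.5 -> quadratic preferred
#>   quadratic optimum at greenness 0.259
```

The quadratic model wins and its optimum (0.259) recovers the greenness the
generator assigned to foraging patches (0.25): cells revisited most sit at
mid-range greenness, with revisitation falling off toward barer and greener
ground alike. On the diel side, a scenario with a full dusk waterhole bias
puts dusk far ahead in waterhole proximity:

```r
sc2 <- generate_scenario(scenario_config(n_individuals = 4, n_days = 48,
  patch_revisit_cycle = 4, patch_dwell = 1, rng_seed = 42))
diel <- standardize_diel_fixes(sc2$trajectories)
waterhole_proximity_counts(diel, sc2$waterholes)
#> # A tibble: 4 × 4
#>   anchor   n_fixes n_near prop_near
#>   <chr>      <int>  <int>     <dbl>
#> 1 dawn         192      1   0.00521
#> 2 dusk         192    106   0.552
#> 3 midday       192      0   0
#> 4 midnight     194      0   0

klocoh_isopleth(filter(sc2$trajectories, individual_id == "SIM01"))
#> <home_range_isopleth> 90% level, k = 30: 21.156 km^2, 771/855 fixes covered (715 hulls)
```

`run_pipeline(pipeline_config(...))` chains every stage (simulate → diel →
recursion → ndvi → annual → homerange) into an output directory with a
hash-carrying manifest; a thin CLI wrapper ships at `exec/rhinomove` in the
installed package (`rhinomove run-all --config cfg.yaml --seed 1 --outdir out`).

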