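---
title: "Mesoscale movement and recursion analysis with rhinomove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale movement and recursion analysis with rhinomove}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhinomove)
library(dplyr)
```

rhinomove analyses recursive movement — an animal's repeated return to
previously visited places — in irregular, gappy GPS telemetry of the kind
collected on large, hard-to-collar herbivores. It works at three nested
temporal scales: a daily displacement cycle, biweekly patch recursion, and
annual returns within a home range. Because relocation data for critically
endangered species are rarely shareable, the package ships a seeded
generator of rhino-like trajectories, waterholes and greenness landscapes so
that every stage of the pipeline can be exercised, calibrated and tested
without sensitive coordinates.

## The diel displacement model

Collared animals rarely deliver fixes on a regular schedule; fix rates vary
from about one per hour to fewer than three per day, with gaps. Rather than
interpolating (which invents data), the analysis standardises each day's
fixes to four diel anchors at local 07:00 (dawn), 13:00 (midday), 19:00
(dusk) and 01:00 (midnight), each with a ±2.5 h selection window. The window
is wide enough to absorb the seasonal drift of sunrise (roughly 06:20–07:30)
and sunset (18:25–19:35) at southern-African latitudes, so no ephemeris is
needed. Within a window the fix closest to the anchor instant wins, ties
going to the earlier fix; the 01:00 window spans the date boundary and
assigns to the date of the anchor instant. The anchor times and tolerance
are configurable (`anchor_config()`); the defaults are chosen because
07/13/19/01 are the unique clock times that give the intended "roughly 6 h"
spacing for a crepuscular animal.

Displacements are then computed between anchor slots a nominal 6, 12 or
24 h apart (24 h pairs the same anchor on consecutive days; 12 h pairs
anchors two slots apart in the midnight–dawn–midday–dusk cycle, in both
directions; 6 h pairs adjacent slots). Because the *actual* elapsed time
between two selected fixes varies around the nominal lag, every displacement
is divided by the exact elapsed hours, giving a rate in m/h. A record whose
elapsed time strays more than twice the anchor tolerance from the nominal
lag is discarded. One fix may legitimately end one record and start the
next; the displacement series overlap by construction.

Distributions of these rates are compared across anchors, seasons
(wet = November–March, dry = April–October, by local month) and sexes with
pairwise two-sample Kolmogorov–Smirnov tests under a Bonferroni correction
(`ks_pairwise()`), and per-individual 24-h series are screened for
periodicity with Fisher's exact g test (below). Proximity to standing water
is tabulated per anchor as the count of diel fixes within an inclusive
250 m radius of the nearest waterhole.

## Time-use grids: nsv and mlsv

Short-term recursion is measured on a square 1 km² grid snapped to whole
kilometres. Cells are half-open on each axis, so a fix sitting exactly on a
shared edge belongs to the higher-index cell — the same convention rasters
use, and the reason a boundary waterhole excludes exactly one cell.

Trajectories are cut into the 16-day compositing calendar used by satellite
greenness products: windows start on day-of-year 1, 17, 33, … 337 of each
year; the truncated 23rd window at the year end is dropped. A window of an
individual's trajectory enters the analysis only if at least 15 of its 16
local calendar dates carry at least one fix (days are counted, not fixes);
this screens out windows whose gaps would bias recursion estimates
downward. No interpolation is performed, so nsv and mlsv remain lower-bound
estimates on gappy data.

Within each qualifying window, the in-cell fix sequence of every visited
cell is split into *separate visits* wherever the gap between successive
in-cell fixes exceeds the inter-visit gap (ivg), 12 h at this scale. The
split is strict — a gap of exactly 12 h does not split — and excursions to
other cells between two in-cell fixes less than 12 h apart do not end a
visit. Two statistics summarise each cell: **nsv**, the number of separate
visits (recursion), and **mlsv**, the mean number of locations per separate
visit (visit duration). mlsv is reported untruncated because it is a mean.
`build_time_use_grid()` is verified against an independent quadratic-time
oracle in the test suite; nsv is non-increasing and mlsv non-decreasing in
the ivg, which the tests also assert.

## Linking recursion to greenness

Each qualifying window's cells are joined to the greenness raster of the
same compositing period. Cell summaries (mean, median, min, max, sd over
the n−1 denominator) are taken over unmasked pixels whose centres fall
inside the cell; with 250 m pixels nesting roughly 16:1 in 1 km cells,
partial-pixel area weighting is immaterial and the centre rule is
deterministic. Cells with no unmasked pixel centre are dropped with a
warning.

The recursion–greenness relationship is characterised by fitting nsv on
mean greenness with and without a quadratic term and comparing AIC
(`recursion_vs_ndvi()`). A foraging system whose preferred patches sit at
mid-range greenness produces a hill: the quadratic wins with negative
curvature, and its implied optimum −b₁/(2b₂) estimates the preferred
greenness. The fits use all visited cells (nsv ≥ 1) so the regression is
estimable even when revisitation is sparse; the accompanying binned density
table — meant for plotting — is restricted to revisited cells (nsv ≥ 2),
since unrevisited cells would swamp the display. AIC is the default
criterion simply because both candidate models are least-squares fits of
the same response; nothing in the comparison depends on that choice of
penalty at these sample sizes.

## Annual recursion and time to return

At the annual scale the same visit machinery runs over the full trajectory
with a 7-day ivg, so daily shuttling within a neighbourhood no longer
counts as separate visits. Cells containing a known waterhole are flagged
and excluded from the return-time analysis — drinking recursion would
otherwise dominate foraging recursion — but they stay in the grid for range
metrics, where their high visitation is itself of interest. For every cell
with at least three visits, the time to return is the gap in days from the
*end* of one visit to the *start* of the next: "time to return" semantically
excludes residence time. Returns are reported in 7-day histogram bins.

Per individual, range size is the number of cells visited at least once;
the mean, median and SD of nsv are computed over cells with at least two
visits; the proportion revisited divides ≥2-visit cells by ≥1-visit cells;
and the top-quartile count is the number of cells at or above the
individual's 75th percentile of nsv over *all* visited cells
(linear-interpolation quantile, ties included — computing the quantile over
all visited cells rather than only revisited ones is the natural reading of
"values observed for that individual", and it is configurable in the code).
Range-size correlations against median nsv, SD of nsv and proportion
revisited use Pearson's r with a Fisher-z 95% interval, with a
leave-one-out rerun available because a single outlier individual can
dominate six-animal correlations.

## k-LoCoH home ranges

Home ranges per 16-day window are estimated with k-nearest-neighbour local
convex hulls: around every fix, the convex hull of it and its k−1 nearest
neighbours (Euclidean; distance ties broken by timestamp order); hulls
sorted by ascending area — the classic local-density proxy — with ties by
enclosed-fix count descending, then focal timestamp; hulls unioned
cumulatively until the union contains at least the requested fraction
(default 90%) of fixes. Containment counts boundary points as covered,
keeping the estimator conservative and deterministic. The union's area is
computed exactly by a vertical slab decomposition: the plane is cut at
every hull vertex and every pairwise edge crossing, within a slab the
union's vertical extent is linear in x, and the trapezoid rule integrates
it without error. The implementation is checked against an independently
coded oracle (separate hull, containment, ordering and union-area
routines) to 10⁻⁹ relative tolerance, and isopleth area is verified to be
non-decreasing in both the level and k.

k is not a property of the data; the default k = ⌈√n⌉ per window is a
widely used heuristic and is exposed in the configuration, with the value
actually used echoed in every result row. All-coincident fixes yield a
flagged zero-area degenerate result rather than an error.

Windows passing the 15-day coverage filter contribute one row each:
log-transformed isopleth area (log m²; areas are strictly positive or the
row is dropped with a warning) and the mean and variance of greenness over
pixel centres inside the isopleth. The area–greenness relationship is
estimated by a Gaussian random-intercept model, `log_area ~ greenness +
(1 | individual)`, fit by REML via lme4 — the standard treatment for
unbalanced repeated measures across individuals. Variance of greenness is
computed and carried but only the mean enters the default model. With a
single individual the model collapses to OLS and says so; singular fits
(random-intercept variance estimated at zero) are allowed and flagged.

## Fisher's exact g test

For short displacement series the periodicity test uses the exact null
distribution of the maximum periodogram ordinate's share of total power.
With ordinates I_k at Fourier frequencies k/n, k = 1…m = ⌊(n−1)/2⌋
(computed after mean removal), the statistic is g = max I / Σ I and

P(G > g) = Σ_{j=1}^{⌊1/g⌋} (−1)^{j−1} C(m, j) (1 − jg)^{m−1},

evaluated in log space for numerical safety. The exact alternating sum is
used rather than the exponential approximation precisely because the
series of interest are short (a month of daily displacements). The test is
invariant to adding a constant and to positive rescaling; on 2,000
white-noise series of length 30 the test suite checks that the rejection
rate at α = 0.05 is 0.05 ± 0.01, and that a noiseless Fourier-frequency
sinusoid yields p < 0.001.

## The synthetic scenario generator

`generate_scenario()` produces trajectories from a biased correlated
random walk at a 1-hour latent resolution. Each animal holds a current
foraging patch and mean-reverts toward it (rate 0.25 h⁻¹ by default) with
Gaussian steps whose scale follows a crepuscular profile (peaks at 06–08
and 18–20 local, troughs at midday and midnight) and a wet-season
multiplier (0.7 in November–March: when resources are plentiful, shorter
movements suffice). With hazard 1/`patch_dwell` per day the animal switches
patch, preferring patches last departed about `patch_revisit_cycle` days
ago — that preference is what makes return times recoverable downstream.
During the dusk window the position jumps near the *nearest* waterhole with
probability `dusk_water_bias` (100 m jitter), emulating post-dusk drinking;
a symmetric `dawn_return_bias` sends the animal to its habitual dawn patch,
emulating faithful morning foraging. Observed fixes are the latent
positions thinned to the mean fix interval, dropped independently with the
dropout probability, and jittered in time — reproducing the 1 h to sub-daily
irregular rates the analyses must tolerate while keeping the generating
truth well defined at the hourly scale.

The greenness landscape is a smoothed Gaussian random field rescaled to a
background mean of 0.20 and SD of 0.12 — spanning the bare-soil-to-shrubland
range typical of semi-arid savanna and, importantly, putting background
greenness on *both* sides of the patch value — with pixels within a
Gaussian footprint (800 m scale) of each patch centre pulled toward the
patch target of 0.25, the mid-range greenness of productive shrub. Rasters
are static across compositing periods by default (an optional sinusoidal
seasonal modulation exists) so that recursion–greenness tests are not
confounded by landscape change. Identical seeds reproduce every output
bit-for-bit.

What the generator does *not* emulate: demographic or energetic state,
competitors and predators, territory boundaries, collar-failure clustering,
spatially correlated dropout, or any fitted resemblance to real rhino
parameters (no speed or range-size estimates are public to fit to). Passing
recovery tests therefore demonstrates that the pipeline detects the
structures it claims to detect when they are present — not that real rhinos
have them.

## Numerical conventions and degenerate inputs

* Coordinates must arrive in a metric projected CRS; the package does no
  geodesy. Timestamps are UTC internally; local clock logic uses a fixed
  configurable offset (default +2).
* Half-open cells `[origin, origin + size)`; 0-based indices; origins
  snapped down to whole multiples of the cell size.
* Visit splitting is strictly greater-than the ivg. Duplicate
  (individual, timestamp) rows collapse to the first with a warning.
* Diel selection ties break to the earlier fix; hull-area ties break by
  enclosed count then focal time; quantiles are type-7.
* Constant series, zero-variance covariates, empty waterhole sets, cells
  with no unmasked pixels, all-coincident fixes and single-group mixed
  models are all either errors with a clear message or flagged degenerate
  results, as documented per function.

## Problem sizes used by the test suite

The suite exercises the oracle equivalences on 200 random trajectories
(≤ 200 fixes) for visit statistics and 100 instances (≤ 50 fixes,
k ∈ {3, 5, 10}) for the hull estimator; calibration runs use 2,000
white-noise series (Fisher's g) and 500 replicates of four 200-observation
groups (KS family-wise error); recovery runs use ten seeded scenarios per
behaviour (45–240 simulated days, 1–6 individuals) and 200 replicates of a
40-group × 10-observation panel for the mixed model. These sizes give the
recovery checks comfortable power while keeping a full test run to a few
minutes on a single core.

## Known limitations

* Return-time estimates inherit the lower-bound caveat of gappy data; no
  gap interpolation is attempted by design.
* The 12-h displacement pairing uses both anchor pairings symmetrically;
  analyses that want only dawn→dusk can filter the record table.
* Isopleth polygons are reported as the set of member hulls (their union is
  the region); consumers needing a dissolved boundary must union them in a
  GIS.
* The annual-scale individual filter is a trajectory-span threshold, not a
  fix-density criterion; very sparse year-long records pass the span check
  but carry weak recursion information.
* Greenness summaries use pixel centres; cells or isopleths smaller than a
  pixel can end up empty and are dropped with a warning.
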