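---
title: "Landscape fire progression, spread metrics, and the Fire Perimeter Effect"
author: "fireprogress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape fire progression, spread metrics, and the Fire Perimeter Effect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireprogress)
```

## The scientific question

Quaking aspen (*Populus tremuloides*) forests are widely believed to slow
or stop wildfire relative to conifer forests: aspen foliage and
understories are moist, canopies are held high, and litter decomposes
quickly. This package implements a complete, testable pipeline for
quantifying that effect from fire-progression data:

1. **Day-of-burning (DOB) interpolation** — given a fire's final
   perimeter and sparse dated satellite-style detections, assign a burn
   day to every 30-m pixel inside the perimeter.
2. **Daily spread metrics** — decompose the DOB map into spatially
   discrete daily patches and compute each day's total area burned
   (hectares) and maximum linear spread (meters).
3. **Vegetation effects on spread** — Gaussian linear mixed models of
   log10-transformed spread metrics on aspen cover (fixed effect), with a
   random intercept per fire event.
4. **The Fire Perimeter Effect (FPE)** — for each cover type and fire,
   compare the type's abundance in a 120-m band around the final
   perimeter with its abundance in the burn interior:
   FPE = (P − I) / (P + I). Positive values mean the type is
   over-represented where the fire *stopped* (a barrier effect). Per-type
   sign tests across fires use the exact two-sided binomial at a
   Bonferroni-adjusted threshold (0.05 / 11 cover types ≈ 0.0045).

Because the real inputs for such a study (satellite active-fire archives,
national fire perimeter and vegetation products, reanalysis weather
grids) are far beyond desk scale, the package ships a
cellular-automaton landscape-fire simulator in which the aspen spread
penalty is the *generative truth*. Every downstream stage is then
testable: the pipeline must recover what the simulator put in.

## The simulator

### Landscapes

`generateLandscape()` thresholds a smoothed Gaussian random field by the
quantiles of the requested class weights. Marginal class frequencies are
exact up to integer rounding (rank-based assignment), and the smoothing
correlation length ("patchiness", meters) controls clump size;
patchiness 0 gives independent cells. The vocabulary is the 11 coarse
cover groups used throughout: aspen, cool conifer, disturbed,
herbaceous, mixed aspen–conifer, nonflammable, prior burn, shrub, warm
conifer, wetland, woodland.

### Fire spread

`simulateFire()` runs a stochastic contact process on the grid with
8-connectivity: an unburned cell adjacent to the burn ignites with
probability

```
baseSpreadProb × perTypeMultiplier[type] × exp(weatherCoupling × (w_t − w̄)) × windFactor
```

clipped to [0, 1]. The per-type multiplier encodes relative flammability;
the defaults put conifer forests at 1.0, aspen at 0.3, nonflammable at
0, prior burns at 0.2, with intermediate values for shrub, woodland and
the other groups. The multiplicative weather factor keeps the
aspen/conifer contrast scale-free while letting a daily fire-weather
index pulse the whole fire.

Three design choices deserve explanation because the defaults were
chosen to reproduce the *scale relations* of real fire mapping, not just
its mechanics:

* **Sub-steps per day** (`subStepsPerDay`, default 1). A real fire
  advances hundreds of meters to kilometers per day — many 30-m cells —
  whereas a single contact-process step advances at most one cell. With
  one step per day, every day's burn is a one-cell-thin shell at the
  same spatial scale as detection noise, which no real daily
  progression map shows. Setting several sub-steps per day (the demo
  uses 5) lets one day's burn form a band several cells deep, restoring
  the relation *daily advance ≫ geolocation error* that the
  interpolation method assumes. The default remains 1 so the elementary
  contract (one ring per day in the deterministic limit) holds exactly.
* **Stopping rule.** The simulation stops at `maxDays` or when no
  ignitable cell remains adjacent to the burn. A day on which no cell
  happens to ignite is a quiet smoldering day — it contributes no burned
  cells (so that day is simply absent from the DOB record, like real
  discontinuous progressions) but does not extinguish the fire. A
  stop-on-first-quiet-day rule would make fire duration exponentially
  short in the daily extinction probability, an artifact that would
  prevent multi-week progressions entirely.
* **Wind** (`windStrength`, default 0). Optionally, spread is
  concentrated on downwind faces via
  `exp(windStrength × (cos(θ − wind_t) − 1))`, where θ is the outward
  spread direction at a cell. This produces the directional runs real
  fires make. All package defaults are isotropic.

### Observation model

`sampleDetections()` thins each day's newly burned cells with
probability `rate/100` (so `rate` is the expected number of detections
per 100 burned cells per day), adds isotropic Gaussian positional jitter,
and keeps the true day. An optional `minPerDay` floor emulates daily
satellite revisits: a real sensor that images the fire every day will
register an active front even on a slow day, so detection counts do not
drop to zero just because little area burned. The demo configuration
uses rate 5, 15-m jitter, and a floor of one detection per burning day.

## Day-of-burning interpolation

`interpolateDOB()` assigns every pixel whose center falls inside the
perimeter the day of its nearest detection (exact Euclidean distance,
point to cell center). Ties resolve to the earlier day; the result is
invariant to detection order. This nearest-detection rule is the
simplest member of the family of DOB interpolators used in the
fire-mapping literature and is pinned for reproducibility; the operation
is a single function boundary, so a k-NN or inverse-distance variant can
be swapped in without touching the rest of the pipeline.

Two properties anchor the implementation:

* with every burned cell detected and zero jitter, the interpolation
  reproduces the simulator's ground truth bit-exactly (the perimeter
  rasterization uses cell-center containment under the even-odd rule, so
  unburned islands are excluded);
* under realistic thinning and jitter, more than 80% of pixels are
  within one day of truth (a regression guard on the demo settings, not
  an external claim).

Fires enter the spread analysis only if they have at least 10 detections
and at least 0.1% aspen within the perimeter (`passesInclusionFilters()`),
both bounds inclusive.

## Spread metrics

`extractPatches()` takes the 8-connected components of each day's pixels
— the spatially discrete DOB patches that are the unit of the spread
analysis. For each patch, `computeSpreadMetrics()` finds the shared
boundary with the cumulative earlier-day footprint; an empty shared
boundary marks a discontinuous day (first day, or a spot-fire
ignition). Maximum linear spread is the greatest distance from the
shared boundary measured in a raster cell of the patch: for every patch
pixel, the exact Euclidean distance (two-pass lower-envelope distance
transform) from its center to the nearest shared-boundary pixel center,
maximized over the patch. Discontinuous patches seed the distance at the
day's earliest detection inside the patch, falling back to the patch
centroid. A "closest non-shared boundary" variant
(`closestBoundarySpread()`) is exposed for comparison but not used in
models, because the maximum-over-cells reading is the one that assigns a
single value to the whole patch.

Daily area is `n_pixels × pixelSize² / 10⁴` hectares.

## Cover types, prior burns, covariates

`reclassify()` collapses a fine vegetation legend into the 11 coarse
groups through an editable two-column CSV mapping; a synthetic stub
legend ships with the package (the real legend for a given landcover
product is data, not algorithm). `applyPriorBurns()` overlays historical
perimeters: cells burned 1–10 years before the focal fire become
`prior_burn`, with the most recent burn taking precedence; same-year
burns are outside the window (the window is taken literally).
When multiple landcover map versions exist, `landcoverVersionFor()`
selects the most recent version preceding the fire year.

Covariates (fire-weather indices, climate, topography) are sampled per
patch from 0.1% random pixels (floor of one), by nearest-cell lookup for
grids coarser than 30 m — mirroring how one "samples" a reanalysis cell
rather than smoothing it. Monthly climate z-scores standardize the fire
ignition month against the pooled April–June monthly values of a
1986–2015 reference (90 values); pooling, rather than a mean of monthly
means, is a documented choice as the convention is not fixed in the
literature. Terrain aspect is circular-transformed to eastness and
northness, with flat cells mapped to (0, 0) by convention.

## Models

Both spread metrics are log-normally distributed, so models use log10
responses; zero-spread patches (no-advance days) are floored at half a
pixel (15 m) before the log. `fitMixed()` fits a Gaussian linear mixed
model with a random intercept per fire (glmmTMB); when the random-effect
fit is singular or fails to converge it falls back to ordinary least
squares with a warning. Marginal and conditional variance explained use
the standard Gaussian variance-partition formulation (fixed-effect
variance over total; fixed plus random over total).

`selectModel()` implements top-down selection around the aspen term:
all candidates enter as first-order terms; covariates with Wald p ≥ 0.05
are dropped; among surviving pairs with Pearson |r| > 0.3 the
individually more predictive term (lower single-term-model AIC) is kept;
aspen × covariate interactions are retained only if significant and
AIC-improving. "Individually more predictive" and the dropping α are
pinned choices — the selection recipe's metric conventions vary across
studies. If the reduced model ends up with a worse AIC than the initial
all-terms model, the initial model is returned (AIC is the fit criterion
throughout), which also guarantees the selected model never has a worse
AIC than the starting point.

Per-fire FPE values are related to fire-season weather and climate by
simple linear models (`fitFpeCovariateLm()`) and to day-of-year by a
penalized thin-plate smooth with basis dimension 10
(`fitFpeDoySmooth()`).

## The Fire Perimeter Effect

`perimeterInteriorMasks()` classifies cells by exact distance from the
cell center to the perimeter polyline: the perimeter band is everything
within 60 m on either side (up to two 30-m pixels each way — wide enough
to capture vegetation that was burned over but contributed to stopping
the fire, and to absorb small mapping errors), and the interior is
everything inside the polygon deeper than 60 m. The band-vs-interior
definition has one genuinely ambiguous reading — interior as *everything*
deeper than the band versus only a 60-m-deep inner ring — so both are
implemented behind the `interior = "full" | "ring"` switch, with "full"
the default. `fpe()` is antisymmetric and scale independent;
`signTest()` uses the exact two-sided binomial (minimum-likelihood
definition, the base-R convention), excluding zero and undefined FPE
values as in the classical sign test; `bonferroniThreshold()` divides α
by the 11 cover types.

## What the synthetic test bed does and does not show

The simulator emulates: categorical 30-m landcover with tunable
abundance and patchiness, cover-dependent stochastic spread with the
aspen penalty as generative truth, pulsed fire weather, sparse jittered
daily detections, final perimeters with unburned islands, and smooth
covariate fields. Passing tests therefore demonstrate that the pipeline
*recovers known generative structure through the full observation
chain* — they do not validate the ecological magnitude of any real-world
effect, which depends on the real archives this package deliberately
does not ingest. Real-data coefficients, medians and sample sizes are
out of scope by design.

Two scale caveats matter when interpreting simulator results. First,
real DOB patches are hundreds to thousands of hectares — far larger than
vegetation grain — whereas desk-scale simulations produce patches of
tens of cells unless sub-steps and the detection floor restore the scale
relations described above. Statistics that condition on patch-level
cover fractions are sensitive to this: a patch of a few cells can only
have aspen shares like 0, 1/3 or 1/2, so share bins mechanically select
on patch size. The package's validation experiments therefore either
compare fires whose landscape aspen fraction differs (between-fire
contrasts) or aggregate to fire-days before binning. Second, the
"maximum" in maximum daily linear spread is order-statistic-like: it is
dominated by the fastest conifer corridor and so responds to aspen
abundance much more weakly than daily area does (the same compression is
visible in the real-data contrast between the two metrics).

## Validation experiments and problem sizes

The test suite runs entirely on synthetic data built at test time. The
main experiments and their sizes, chosen to exercise each claim at the
smallest scale where it is statistically meaningful:

* parameter recovery: 40 fires × 20 patches with a known aspen slope;
  coverage of a zero slope over 100 replicates of 20 fires × 10 patches;
* aspen-bin shape: 20 fires (seven aspen-poor, six intermediate, seven
  aspen-rich landscapes) on 260 × 260 grids, six spread sub-steps per
  day, one shared regional weather series, dense daily detections
  (25 per 100 cells, 10-m jitter); the fire-day totals of daily area
  and the fire-day maxima of linear spread, binned by the day's
  area-weighted aspen share;
* barrier property: 20 fires inside closed zero-flammability aspen
  rings; aspen FPE positive in every fire and Bonferroni-significant by
  sign test;
* oracle equivalence: the distance-transform spread metric against
  brute-force all-pairs distances on random patches; the exact binomial
  sign test against direct probability-mass enumeration for all n ≤ 25;
* DOB round trip: dense unjittered detections reproduce simulator truth
  bit-exactly on the demo fires.

## Numerical choices

Distances are exact Euclidean between cell centers (no chamfer
approximation); perimeter-band membership is by exact point-to-segment
distance to the boundary polyline. DOB ties go to the earlier day.
Connected components, patch adjacency and the simulator's neighborhood
all use 8-connectivity — one consistent topology avoids leak paradoxes
between spread and patch extraction. All random streams are derived from
a master seed plus string tags (fire id, operation), so adding fires
never perturbs existing ones and every generator is bit-reproducible.
Rasters are written as ESRI ASCII grids (plain text, single band,
GDAL-readable), perimeters as GeoJSON under the even-odd rule (holes are
simply additional rings), detections and legends as CSV.

## Known limitations

No physical fire behavior (no fuel-moisture dynamics, no crown-fire
initiation), no sub-daily timing, no sensor footprints or confidence
weighting, no real-product ingestion. The simulator's flammability
multipliers are calibration knobs with defensible ordering, not
estimates. FPE is sensitive when a cover type's abundance is very low,
exactly as in real data. The fire-inclusion size selection in the demo
pipeline (re-attempting ignitions until a burn is large enough to map)
mirrors the fact that fire archives contain only fires that grew, and
conditions the simulated population accordingly.
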