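# fireprogress

Tools for landscape fire-progression analysis: how does vegetation —
quaking aspen in particular — shape how fast a wildfire grows and where
it finally stops?

The package is aimed at fire ecologists and spatial ecoinformaticians
working with daily fire-progression maps. It implements, as tested R
functions:

* **Day-of-burning (DOB) interpolation.** Every 30-m pixel inside a
  fire's final perimeter is assigned the day of its nearest dated
  detection (`interpolateDOB()`), with the standard inclusion filters
  (≥ 10 detections, ≥ 0.1% aspen; `passesInclusionFilters()`).
* **Daily spread metrics.** The DOB map is decomposed into spatially
  discrete daily patches (8-connected components,
  `extractPatches()`); each patch gets its daily area burned
  (ha) and its maximum linear spread — the greatest raster-cell distance
  from the boundary shared with the previous day's burn, computed with
  an exact Euclidean distance transform (`maxLinearSpread()`).
  Spot-fire days with no shared boundary are flagged discontinuous and
  seeded at the day's earliest detection.
* **Cover types.** Fine vegetation legends collapse to 11 coarse groups
  (`reclassify()`), recent prior burns (1–10 years) overlay as their own
  class (`applyPriorBurns()`), and proportions are computed over any
  pixel set (`coverProportions()`).
* **The Fire Perimeter Effect.** For a cover type with perimeter-band
  proportion P (within 60 m either side of the perimeter line) and burn
  interior proportion I,

  FPE = (P − I) / (P + I)  ∈ [−1, 1].

  FPE > 0 means the type is over-represented where the fire stopped — a
  barrier effect. Per-type sign tests across fires use the exact
  two-sided binomial at the Bonferroni threshold α/11
  (`fpeTable()`, `signTest()`, `bonferroniThreshold()`).
* **Spread models.** Gaussian linear mixed models of log10 daily area
  and log10 linear spread on aspen cover with a fire-level random
  intercept (`fitMixed()`), per-cover-type contrasts
  (`fitCoverContrasts()`), top-down covariate selection with
  Pearson-r > 0.3 collinearity pruning by AIC (`selectModel()`), FPE ~
  weather linear models and an FPE ~ day-of-year penalized smooth
  (`fitFpeDoySmooth()`).
* **A synthetic test bed.** A cellular-automaton landscape-fire
  simulator (`generateLandscape()`, `simulateFire()`,
  `sampleDetections()`, `generateCovariateGrid()`) in which the aspen
  spread penalty is generative truth, so the entire pipeline
  (`runAll()`) is testable end-to-end without any satellite, perimeter
  or vegetation downloads.

Rasters are read and written as plain-text ESRI ASCII grids
(GDAL-readable), perimeters as GeoJSON (even-odd rule; holes are just
additional rings), detections and legend mappings as CSV.

## Worked example

Simulate a fire ignited inside a closed aspen ring of zero flammability,
then score the Fire Perimeter Effect:

```r
library(fireprogress)

spec <- GridSpec(60, 60)                       # 60 x 60 cells of 30 m
cls <- matrix("warm_conifer", 60, 60)
cheb <- pmax(abs(row(cls) - 30), abs(col(cls) - 30))
cls[cheb >= 18 & cheb <= 20] <- "aspen"        # a closed aspen annulus
lc <- LandcoverGrid(spec, cls)

params <- SpreadParams(baseSpreadProb = 0.5, aspen = 0,
                       subStepsPerDay = 2, maxDays = 40, rngSeed = 501)
fire <- simulateFire(lc, c(30, 30), params, fireId = "ring01")

tab <- fpeTable(fire, lc)
tab[tab$group %in% c("aspen", "warm_conifer"), ]
#>  fire_id        group perimeter_prop interior_prop    fpe
#>   ring01        aspen          0.525             0  1.000
#>   ring01 warm_conifer          0.475             1 -0.356
```

The fire fills the conifer interior and stops at the ring, so aspen
makes up 52.5% of the 120-m perimeter band but 0% of the burn interior:
its FPE is 1 (maximal barrier effect), while the conifer that actually
burned scores negative. The statistic's worked values:

```r
fpe(0.2, 0.1)                 # a type twice as common at the perimeter
#> 0.3333333
impliedAbundanceExcess(0.18)  # FPE 0.18 ~ 44% more abundant at perimeters
#> 43.90244
bonferroniThreshold()         # 0.05 / 11 cover types
#> 0.004545455
signTest(c(rep(1, 217), rep(-1, 94)))$pValue
#> 2.38e-12
```

For a full synthetic study — six fires, landscapes spanning a gradient
of aspen abundance, detection sampling, DOB interpolation, patch
metrics, FPE tables and mixed models, with a checksummed manifest —

```r
manifest <- runAll(defaultRunConfig(seed = 1), outDir = "demo")
```

writes `patches.csv`, `fpe_records.csv`, `fpe_sign_tests.csv` and
`model_report.txt` under `demo/`; re-running with the same config
reproduces identical checksums. A thin command-line wrapper is in
`inst/scripts/fireprogress.R`.

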