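test_that("FPE follows the formula, antisymmetry, and scale independence", {
  expect_equal(fpe(0.2, 0.1), 1 / 3)
  expect_equal(fpe(0.1, 0.1), 0)
  expect_equal(fpe(0.3, 0), 1)
  expect_true(is.na(fpe(0, 0)))
  expect_error(fpe(1.2, 0.1), "0, 1")
  set.seed(5)
  p <- runif(50); q <- runif(50)
  expect_equal(fpe(p, q), -fpe(q, p))
  c <- 0.37
  expect_equal(fpe(c * p, c * q), fpe(p, q))
  expect_true(all(abs(fpe(p, q)) <= 1))
})

test_that("implied abundance excess inverts the FPE", {
  expect_equal(round(impliedAbundanceExcess(0.18)), 44)
  expect_equal(impliedAbundanceExcess(1 / 3), 100)
  expect_equal(impliedAbundanceExcess(0), 0)
  expect_error(impliedAbundanceExcess(1), "< 1")
  # round trip: fpe of (1 + e/100) vs 1 recovers the excess
  for (f in c(-0.6, -0.18, 0.05, 0.44)) {
    e <- impliedAbundanceExcess(f)
    expect_equal(fpe((1 + e / 100) / (2 + e / 100), 1 / (2 + e / 100)), f,
                 tolerance = 1e-9)
  }
})

test_that("bonferroni threshold is alpha over k", {
  expect_equal(round(bonferroniThreshold(0.05, 11), 4), 0.0045)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.10, 5), 0.02)
})

test_that("sign test counts, excludes ties/undefined, and matches binom", {
  st <- signTest(c(rep(0.5, 217), rep(-0.5, 94)))
  expect_equal(st$nPos, 217)
  expect_equal(st$nNeg, 94)
  expect_lt(st$pValue, 0.001)
  expect_true(st$significant)
  even <- signTest(c(rep(1, 5), rep(-1, 5)))
  expect_equal(even$pValue, 1.0)
  oneSided <- signTest(rep(0.2, 10))
  expect_equal(oneSided$pValue, 2 * 0.5^10)
  ties <- signTest(c(1, -1, 0, NA, 0.5))
  expect_equal(ties$nExcluded, 2)
  expect_true(is.na(signTest(c(0, NA))$pValue))
})

test_that("sign test equals pmf enumeration for all n <= 25", {
  for (n in 1:25) for (k in 0:n) {
    st <- signTest(c(rep(1, k), rep(-1, n - k)))
    expect_equal(st$pValue, min(1, brutePSign(k, n)), tolerance = 1e-10)
  }
})

test_that("perimeter band and interior are disjoint and correctly sized", {
  spec <- GridSpec(120, 120)
  rings <- rectRings(spec, 11, 110, 11, 110)  # 3 km x 3 km fire
  m <- perimeterInteriorMasks(rings, spec, 60)
  expect_length(intersect(m$perimeterSet, m$interiorSet), 0)
  expect_false(m$emptyInterior)
  # the band is two cells wide on each side of the boundary: cells at rows
  # 9..12 flank the northern edge (centers within 60 m of the line)
  expect_true(all(rectIdx(spec, 9, 12, 40, 60) %in% m$perimeterSet))
  expect_false(any(rectIdx(spec, 8, 8, 40, 60) %in% m$perimeterSet))
  expect_false(any(rectIdx(spec, 13, 13, 40, 60) %in% m$perimeterSet))
  # interior excludes the band but fills the deep burn
  expect_true(all(rectIdx(spec, 14, 107, 14, 107) %in% m$interiorSet))
  # degenerate: fire too small to have an interior at 60 m
  small <- rectRings(GridSpec(10, 10), 4, 6, 4, 6)
  ms <- perimeterInteriorMasks(small, GridSpec(10, 10), 60)
  expect_true(ms$emptyInterior)
})

test_that("the ring interior mode keeps only the next 60 m inward", {
  spec <- GridSpec(60, 60)
  rings <- rectRings(spec, 6, 55, 6, 55)
  full <- perimeterInteriorMasks(rings, spec, 60, interior = "full")
  ringm <- perimeterInteriorMasks(rings, spec, 60, interior = "ring")
  expect_true(all(ringm$interiorSet %in% full$interiorSet))
  expect_lt(length(ringm$interiorSet), length(full$interiorSet))
})

test_that("fpeTable scores over-represented edge cover positive", {
  spec <- GridSpec(60, 60)
  cls <- matrix("warm_conifer", 60, 60)
  cheb <- pmax(abs(row(cls) - 30.5), abs(col(cls) - 30.5))
  cls[cheb >= 18 & cheb <= 22] <- "aspen"   # aspen collar at the edge
  lc <- LandcoverGrid(spec, cls)
  mask <- matrix(FALSE, 60, 60)
  mask[cheb <= 19] <- TRUE                   # fire stops inside the collar
  fire <- FireEvent("ringfire", maskToRings(mask, spec))
  tab <- fpeTable(fire, lc)
  expect_equal(nrow(tab), 11)
  a <- tab[tab$group == "aspen", ]
  w <- tab[tab$group == "warm_conifer", ]
  expect_gt(a$fpe, 0)
  expect_lt(w$fpe, 0)
  expect_equal(a$fpe,
               (a$perimeter_prop - a$interior_prop) /
                 (a$perimeter_prop + a$interior_prop))
})

test_that("group summaries apply the Bonferroni threshold", {
  fpeT <- do.call(rbind, lapply(1:30, function(i)
    data.frame(fire_id = paste0("f", i), group = coverTypes(),
               perimeter_prop = NA, interior_prop = NA,
               fpe = c(rep(0.4, 10), -0.4)[order(c(1:10, 11))] *
                 rep(1, 11), stringsAsFactors = FALSE)))
  sg <- signTestByGroup(fpeT)
  expect_equal(nrow(sg), 11)
  expect_equal(attr(sg, "threshold"), 0.05 / 11)
  expect_true(all(sg$significant[sg$group == "aspen"]))
})
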