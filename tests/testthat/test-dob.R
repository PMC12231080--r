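test_that("a single detection floods the whole perimeter with its day", {
  spec <- GridSpec(10, 10)
  rings <- rectRings(spec, 2, 9, 2, 9)
  det <- data.frame(x = 150, y = 150, day = 5L, sensor = "t")
  fire <- FireEvent("one", rings, det)
  dob <- interpolateDOB(fire, spec)
  d <- dayMatrix(dob)
  expect_true(all(d[!is.na(d)] == 5L))
  expect_equal(sum(!is.na(d)), 64)
})

test_that("two detections split a rectangle at the Voronoi bisector", {
  spec <- GridSpec(10, 20)
  rings <- rectRings(spec, 1, 10, 1, 20)
  # day 1 at x = 0, day 2 at x = 300: bisector at x = 150 (column 5/6 edge)
  det <- data.frame(x = c(0, 300), y = c(150, 150), day = 1:2, sensor = "t")
  fire <- FireEvent("bisect", rings, det)
  d <- dayMatrix(interpolateDOB(fire, spec))
  expect_true(all(d[, 1:5] == 1L))
  expect_true(all(d[, 6:20] == 2L))
})

test_that("exact distance ties resolve to the earlier day", {
  spec <- GridSpec(1, 3)
  rings <- rectRings(spec, 1, 1, 1, 3)
  # cell centers at x = 15, 45, 75; the middle cell is equidistant
  det <- data.frame(x = c(15, 75), y = c(15, 15), day = c(3L, 2L),
                    sensor = "t")
  fire <- FireEvent("tie", rings, det)
  d <- dayMatrix(interpolateDOB(fire, spec))
  expect_equal(as.integer(d), c(3L, 2L, 2L))
})

test_that("interpolation is invariant to detection order", {
  set.seed(8)
  spec <- GridSpec(25, 25)
  rings <- rectRings(spec, 2, 24, 2, 24)
  det <- data.frame(x = runif(30, 50, 700), y = runif(30, 50, 700),
                    day = sample(1:6, 30, replace = TRUE), sensor = "t")
  a <- interpolateDOB(FireEvent("o1", rings, det), spec)
  b <- interpolateDOB(FireEvent("o2", rings, det[sample(30), ]), spec)
  expect_identical(dayMatrix(a), dayMatrix(b))
})

test_that("dense unjittered detections reproduce simulator truth exactly", {
  lc <- uniformLandcover(45, 45)
  p <- SpreadParams(baseSpreadProb = 0.35, maxDays = 14, rngSeed = 5)
  f <- simulateFire(lc, c(23, 23), p, fireId = "dense")
  det <- sampleDetections(f@trueDob, rate = 1e6, jitterSigma = 0, seed = 1)
  f@detections <- det
  dob <- interpolateDOB(f, gridSpec(lc))
  expect_identical(dayMatrix(dob), dayMatrix(f@trueDob))
})

test_that("thinned jittered detections still recover most days within 1", {
  lc <- generateLandscape(GridSpec(80, 80),
                          c(aspen = 0.15, warm_conifer = 0.85),
                          patchiness = 120, seed = 2)
  p <- SpreadParams(baseSpreadProb = 0.3, weatherCoupling = 0.4,
                    subStepsPerDay = 5, maxDays = 12, rngSeed = 2)
  set.seed(2)
  w <- as.numeric(stats::filter(rnorm(12), 0.7, "recursive"))
  f <- simulateFire(lc, c(40, 40), p, w, fireId = "jit")
  det <- sampleDetections(f@trueDob, rate = 15, jitterSigma = 15, seed = 2,
                          minPerDay = 1)
  f@detections <- det
  dob <- interpolateDOB(f, gridSpec(lc))
  truth <- dayMatrix(f@trueDob)
  est <- dayMatrix(dob)
  both <- !is.na(truth) & !is.na(est)
  expect_gt(mean(abs(est[both] - truth[both]) <= 1), 0.8)
})

test_that("inclusion filters require 10 detections and 0.1% aspen", {
  spec <- GridSpec(30, 30)
  cls <- matrix("warm_conifer", 30, 30)
  cls[1:10, 1:14] <- "aspen"   # well above 0.1% inside any big perimeter
  lc <- LandcoverGrid(spec, cls)
  rings <- rectRings(spec, 1, 30, 1, 30)
  mkFire <- function(n) {
    det <- data.frame(x = seq(20, 800, length.out = n),
                      y = rep(450, n), day = rep(1L, n), sensor = "t")
    FireEvent("f", rings, det)
  }
  few <- passesInclusionFilters(mkFire(9), lc)
  expect_false(few$pass)
  expect_equal(few$reasons, "detections")
  lcNoAspen <- uniformLandcover(30, 30)
  noAspen <- passesInclusionFilters(mkFire(50), lcNoAspen)
  expect_false(noAspen$pass)
  expect_equal(noAspen$reasons, "aspen")
  # boundary inclusive: exactly 10 detections, exactly 0.1% aspen
  clsB <- matrix("warm_conifer", 30, 30)
  clsB[1, 1] <- "aspen"  # 1 / 900 > 0.001
  lcB <- LandcoverGrid(spec, clsB)
  expect_true(passesInclusionFilters(mkFire(10), lcB)$pass)
  clsE <- matrix("warm_conifer", 30, 30)
  spec2 <- GridSpec(25, 40)
  clsE2 <- matrix("warm_conifer", 25, 40)
  clsE2[1, 1] <- "aspen"  # 1/1000 = 0.001 exactly
  lcE <- LandcoverGrid(spec2, clsE2)
  rings2 <- rectRings(spec2, 1, 25, 1, 40)
  det10 <- data.frame(x = seq(20, 1100, length.out = 10), y = rep(300, 10),
                      day = rep(1L, 10), sensor = "t")
  expect_true(passesInclusionFilters(FireEvent("e", rings2, det10), lcE)$pass)
})

test_that("zero detections is an error", {
  spec <- GridSpec(5, 5)
  rings <- rectRings(spec, 1, 5, 1, 5)
  fire <- FireEvent("none", rings)
  expect_error(interpolateDOB(fire, spec), "zero detections")
})
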