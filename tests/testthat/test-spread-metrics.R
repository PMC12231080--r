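test_that("patch extraction partitions burned pixels by day and component", {
  spec <- GridSpec(12, 12)
  day <- matrix(NA_integer_, 12, 12)
  day[2:5, 2:5] <- 1L          # one blob
  day[8:10, 8:10] <- 2L        # second day blob
  day[2:3, 9:10] <- 2L         # detached same-day blob (> 1 diagonal gap)
  dob <- DOBGrid(spec, day)
  pa <- extractPatches(dob, "px")
  expect_equal(length(pa), 3L)
  expect_equal(sum(vapply(pa, function(p) length(p@pixels), integer(1))),
               sum(!is.na(day)))
  days <- vapply(pa, function(p) p@day, integer(1))
  expect_equal(sort(days), c(1L, 2L, 2L))
  # single day, single blob
  one <- extractPatches(DOBGrid(spec,
    matrix(rep(c(NA, 1L), c(72, 72)), 12, 12)), "one")
  expect_equal(length(one), 1L)
})

test_that("diagonal contact joins a component under 8-connectivity", {
  spec <- GridSpec(6, 6)
  day <- matrix(NA_integer_, 6, 6)
  day[2, 2] <- 1L; day[3, 3] <- 1L  # touch at a corner
  pa <- extractPatches(DOBGrid(spec, day), "d")
  expect_equal(length(pa), 1L)
  day2 <- matrix(NA_integer_, 6, 6)
  day2[2, 2] <- 1L; day2[4, 4] <- 1L  # gap of one full cell
  expect_equal(length(extractPatches(DOBGrid(spec, day2), "d")), 2L)
})

test_that("shared boundary marks pixels adjacent to earlier burn", {
  spec <- GridSpec(8, 12)
  day <- matrix(NA_integer_, 8, 12)
  day[, 1:4] <- 1L
  day[, 5:8] <- 2L
  dob <- DOBGrid(spec, day)
  pa <- extractPatches(dob, "sb")
  p2 <- pa[[which(vapply(pa, function(p) p@day, integer(1)) == 2L)]]
  prior <- which(!is.na(day) & day < 2L)
  sh <- sharedBoundary(p2, prior, spec)
  # exactly the western column of the day-2 patch abuts day 1
  expect_setequal(sh, rectIdx(spec, 1, 8, 5, 5))
  # isolated spot fire: empty shared boundary
  expect_length(sharedBoundary(p2, integer(0), spec), 0)
  # patch fully enclosed by prior burn shares its whole outer ring
  day3 <- matrix(1L, 8, 12); day3[4:5, 6:7] <- 3L
  dob3 <- DOBGrid(spec, day3)
  pa3 <- extractPatches(dob3, "enc")
  p3 <- pa3[[which(vapply(pa3, function(p) p@day, integer(1)) == 3L)]]
  sh3 <- sharedBoundary(p3, which(day3 == 1L), spec)
  expect_setequal(sh3, p3@pixels)  # 2x2 patch: every pixel on the ring
})

test_that("max linear spread matches closed forms on line and square", {
  # 1 x 10 strip, shared boundary = westmost pixel: 9 gaps x 30 m
  spec <- GridSpec(1, 10)
  day <- matrix(1L, 1, 10)
  pa <- extractPatches(DOBGrid(spec, day), "strip")[[1]]
  sh <- pa@pixels[1]  # column-major: first index is (1,1)
  expect_equal(maxLinearSpread(pa, sh, NULL, spec), 270)
  # discontinuous 3x3 with central detection: corner distance 30 * sqrt(2)
  spec2 <- GridSpec(5, 5)
  day2 <- matrix(NA_integer_, 5, 5); day2[2:4, 2:4] <- 1L
  pa2 <- extractPatches(DOBGrid(spec2, day2), "sq")[[1]]
  ctr <- cellCenters(spec2, cellIndexAt(spec2, 75, 75))
  det <- data.frame(x = 75, y = 75, day = 1L, sensor = "t")
  expect_equal(maxLinearSpread(pa2, integer(0), det, spec2), 30 * sqrt(2),
               tolerance = 1e-12)
  # patch identical to its shared boundary: zero advance
  expect_equal(maxLinearSpread(pa2, pa2@pixels, NULL, spec2), 0)
})

test_that("distance transform equals brute force on random patches", {
  set.seed(21)
  for (rep in 1:12) {
    nr <- sample(4:14, 1); nc <- sample(4:14, 1)
    spec <- GridSpec(nr, nc)
    n <- nr * nc
    pix <- sort(sample(n, sample(5:min(n, 60), 1)))
    shared <- sort(sample(pix, sample(seq_len(min(5, length(pix))), 1)))
    patch <- new("DOBPatch", fireId = "o", day = 2L,
                 pixels = as.integer(pix), areaHa = 0,
                 maxLinearSpreadM = NA_real_, discontinuous = NA,
                 coverage = numeric(0), covariates = numeric(0))
    got <- maxLinearSpread(patch, shared, NULL, spec)
    expect_equal(got, bruteMaxSpread(pix, shared, spec), tolerance = 1e-9)
  }
})

test_that("spread distances are invariant to translation and rotation", {
  base <- matrix(FALSE, 9, 9)
  base[2:4, 2:7] <- TRUE; base[5:6, 2:3] <- TRUE  # an L-shape
  sharedMask <- matrix(FALSE, 9, 9); sharedMask[2:4, 2] <- TRUE
  measure <- function(m, sm, spec) {
    pix <- which(m)
    p <- new("DOBPatch", fireId = "t", day = 2L, pixels = as.integer(pix),
             areaHa = 0, maxLinearSpreadM = NA_real_, discontinuous = NA,
             coverage = numeric(0), covariates = numeric(0))
    maxLinearSpread(p, which(sm), NULL, spec)
  }
  spec <- GridSpec(9, 9)
  ref <- measure(base, sharedMask, spec)
  # translation within a larger grid
  big <- matrix(FALSE, 15, 15); bigS <- matrix(FALSE, 15, 15)
  big[5:13, 4:12][which(base, arr.ind = TRUE)] <- TRUE
  bigS[5:13, 4:12][which(sharedMask, arr.ind = TRUE)] <- TRUE
  expect_equal(measure(big, bigS, GridSpec(15, 15)), ref)
  # 90-degree rotation
  rot <- t(base)[, 9:1]; rotS <- t(sharedMask)[, 9:1]
  expect_equal(measure(rot, rotS, spec), ref)
})

test_that("daily area follows the pixel count and pixel size", {
  expect_equal(dailyArea(100, 30), 9)
  expect_equal(dailyArea(1, 30), 0.09)
  expect_equal(dailyArea(12356, 30), 1112.04)
})

test_that("metrics pipeline flags discontinuous days and sums areas", {
  spec <- GridSpec(20, 20)
  day <- matrix(NA_integer_, 20, 20)
  day[8:12, 2:6] <- 1L
  day[8:12, 7:8] <- 2L
  day[3:5, 15:17] <- 3L  # spot fire
  dob <- DOBGrid(spec, day)
  pa <- computeSpreadMetrics(extractPatches(dob, "m"), dob, NULL)
  tab <- patchTable(pa)
  expect_equal(sum(tab$n_pixels), sum(!is.na(day)))
  expect_true(tab$discontinuous[tab$day == 1])   # first day has no prior
  expect_false(tab$discontinuous[tab$day == 2])
  expect_true(tab$discontinuous[tab$day == 3])   # detached spot fire
  expect_gt(tab$max_linear_spread_m[tab$day == 2], 0)
})

test_that("alternative closest-boundary statistic is finite and smaller", {
  spec <- GridSpec(10, 10)
  day <- matrix(NA_integer_, 10, 10)
  day[3:8, 3:8] <- 2L
  pa <- extractPatches(DOBGrid(spec, day), "alt")[[1]]
  sh <- pa@pixels[cellCenters(spec, pa@pixels)[, 1] < 3 * 30 + 1]
  mx <- maxLinearSpread(pa, sh, NULL, spec)
  alt <- closestBoundarySpread(pa, sh, spec)
  expect_true(is.finite(alt))
  expect_lte(alt, mx)
  expect_true(is.na(closestBoundarySpread(pa, integer(0), spec)))
})
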