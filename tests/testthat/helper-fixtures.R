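# Small deterministic builders shared across tests.

uniformLandcover <- function(nr, nc, type = "warm_conifer", pixelSize = 30) {
  spec <- GridSpec(nr, nc, pixelSize)
  LandcoverGrid(spec, matrix(type, nr, nc))
}

# rectangular mask [r1..r2] x [c1..c2] as rings on a grid
rectRings <- function(spec, r1, r2, c1, c2) {
  m <- matrix(FALSE, spec@nRows, spec@nCols)
  m[r1:r2, c1:c2] <- TRUE
  maskToRings(m, spec)
}

# linear (column-major) indices of a rectangle
rectIdx <- function(spec, r1, r2, c1, c2) {
  as.integer(outer((r1:r2), (c1:c2) - 1L, function(r, c) c * spec@nRows + r))
}

# a landcover grid with a closed aspen Chebyshev annulus in conifer matrix
aspenRingLandcover <- function(n = 60, center = n / 2, inner = 18, outer = 20) {
  spec <- GridSpec(n, n)
  cls <- matrix("warm_conifer", n, n)
  cheb <- pmax(abs(row(cls) - center), abs(col(cls) - center))
  cls[cheb >= inner & cheb <= outer] <- "aspen"
  LandcoverGrid(spec, cls)
}

# brute-force oracle for max linear spread, continuous case: max over patch
# pixels of min distance to a shared-boundary pixel center
bruteMaxSpread <- function(patchIdx, sharedIdx, spec) {
  a <- cellCenters(spec, patchIdx)
  b <- cellCenters(spec, sharedIdx)
  d <- vapply(seq_len(nrow(a)), function(i)
    min(sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2)), numeric(1))
  max(d)
}

# brute-force two-sided exact binomial p at p0 = 0.5 (minimum-likelihood sum)
brutePSign <- function(k, n) {
  pm <- dbinom(0:n, n, 0.5)
  sum(pm[pm <= pm[k + 1] * (1 + 1e-7)])
}
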