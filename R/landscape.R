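# Synthetic landscape generation: smoothed Gaussian random fields
# thresholded into cover classes by weight quantiles.

#' Derive an independent sub-seed from a base seed and tags
#'
#' Hashes the base seed together with any string tags (fire id, operation
#' name, ...) into a reproducible integer seed below 2^31. Every random
#' stage in the package derives its stream this way, so streams are
#' independent per (fire, operation) and adding fires never perturbs
#' existing ones.
#'
#' @param seed integer base seed
#' @param ... tags folded into the stream (coerced to character)
#' @return A single integer seed.
#' @export
#' @examples
#' deriveSeed(1, "fire_01", "detections")
deriveSeed <- function(seed, ...) {
  key <- paste(c(format(seed), as.character(c(...))), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# Separable Gaussian smoothing with edge replication; sigma in cells.
gaussianSmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  sm1 <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    stats::convolve(vp, k, type = "filter")
  }
  m2 <- apply(m, 2, sm1)
  t(apply(m2, 1, sm1))
}

#' Generate a synthetic categorical landcover raster
#'
#' Thresholds a smoothed Gaussian random field into cover classes by the
#' quantiles of the requested class weights, so marginal class frequencies
#' match the weights (rank-based assignment makes them exact up to integer
#' rounding) while the smoothing correlation length controls spatial
#' patchiness. With \code{patchiness = 0} cells are independent.
#'
#' @param spec a [GridSpec-class]
#' @param classWeights named numeric over (a subset of) [coverTypes()];
#'   nonnegative, summing to 1
#' @param patchiness spatial correlation length in meters (>= 0)
#' @param seed integer seed; output is bit-reproducible given (seed,
#'   parameters)
#' @return A [LandcoverGrid-class].
#' @export
#' @examples
#' lc <- generateLandscape(GridSpec(50, 50),
#'   c(aspen = 0.25, warm_conifer = 0.75), patchiness = 150, seed = 1)
generateLandscape <- function(spec, classWeights, patchiness = 0, seed = 1) {
  bad <- setdiff(names(classWeights), coverTypes())
  if (length(bad))
    stop("unknown cover class(es) in weights: ", paste(bad, collapse = ", "))
  if (any(classWeights < 0)) stop("class weights must be nonnegative")
  if (abs(sum(classWeights) - 1) > 1e-9) stop("class weights must sum to 1")
  if (patchiness < 0) stop("patchiness must be >= 0")
  # canonical ordering so results do not depend on the order weights are given
  w <- classWeights[order(match(names(classWeights), coverTypes()))]
  n <- nCells(spec)
  set.seed(deriveSeed(seed, "landscape"))
  field <- matrix(stats::rnorm(n), spec@nRows, spec@nCols)
  if (patchiness > 0)
    field <- gaussianSmooth(field, patchiness / spec@pixelSize)
  rk <- rank(field, ties.method = "first")
  breaks <- round(cumsum(w) * n)
  breaks[length(breaks)] <- n
  cls <- findInterval(rk, c(0, breaks), left.open = TRUE)
  codes <- match(names(w), coverTypes())
  LandcoverGrid(spec, matrix(codes[cls], spec@nRows, spec@nCols))
}

#' Generate smooth daily covariate fields
#'
#' Produces one smooth correlated field per day: a persistent spatial base
#' field plus a smaller day-specific smooth anomaly plus an additive daily
#' trend. Stands in for gridded daily fire-weather or climate layers. The
#' covariate name is folded into the random stream, so different names give
#' independent fields under the same seed.
#'
#' @param spec a [GridSpec-class]
#' @param name covariate name (e.g. "FWI")
#' @param nDays number of daily fields
#' @param spatialScale correlation length in meters (> 0)
#' @param dailyTrend additive trend per day applied uniformly (field units
#'   per day)
#' @param seed integer seed
#' @return List of nDays numeric matrices.
#' @export
generateCovariateGrid <- function(spec, name, nDays, spatialScale = 300,
                                  dailyTrend = 0, seed = 1) {
  if (spatialScale <= 0) stop("spatialScale must be > 0")
  set.seed(deriveSeed(seed, "covariate", name))
  sig <- spatialScale / spec@pixelSize
  std <- function(m) {
    s <- stats::sd(m)
    if (s > 0) (m - mean(m)) / s else m * 0
  }
  base <- std(gaussianSmooth(
    matrix(stats::rnorm(nCells(spec)), spec@nRows, spec@nCols), sig))
  lapply(seq_len(nDays), function(d) {
    anom <- std(gaussianSmooth(
      matrix(stats::rnorm(nCells(spec)), spec@nRows, spec@nCols), sig))
    base + 0.3 * anom + dailyTrend * (d - 1)
  })
}
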