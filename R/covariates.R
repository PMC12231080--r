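# Sampling gridded covariates into per-patch summaries; monthly climate
# z-scores and topographic transforms.

#' Random pixel subsample of a patch
#'
#' Uniform random subset of size max(1, round(fraction * n)); the 0.001
#' default mirrors sampling 0.1 percent of 30-m pixels per day of fire
#' spread to limit spatial autocorrelation.
#'
#' @param pixels integer vector of cell indices
#' @param fraction sampling fraction in (0, 1]
#' @param seed integer seed (deterministic given (seed, pixels))
#' @return Integer vector of sampled indices.
#' @export
samplePixels <- function(pixels, fraction = 0.001, seed = 1) {
  if (!length(pixels)) stop("pixel set is empty")
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  n <- max(1L, round(fraction * length(pixels)))
  set.seed(deriveSeed(seed, "samplePixels"))
  if (n >= length(pixels)) return(pixels)
  sort(sample(pixels, n))
}

#' A covariate raster with its own geometry
#'
#' Wraps a value matrix and its [GridSpec-class] so coarse grids (e.g.
#' 31-km weather reanalysis) can be sampled at 30-m pixel centers by
#' nearest-cell lookup.
#'
#' @param values numeric matrix
#' @param spec the grid geometry of \code{values}
#' @return A list of class "covariateGrid".
#' @export
covariateGrid <- function(values, spec) {
  stopifnot(all(dim(values) == c(spec@nRows, spec@nCols)))
  structure(list(values = values, spec = spec), class = "covariateGrid")
}

# nearest-cell lookup of a covariate grid at planar coordinates; points
# beyond the grid edge snap to the nearest edge cell
covariateAt <- function(grid, x, y) {
  sp <- grid$spec
  cl <- pmin(sp@nCols, pmax(1, floor((x - sp@originX) / sp@pixelSize) + 1))
  r <- pmin(sp@nRows, pmax(1, floor((sp@originY - y) / sp@pixelSize) + 1))
  grid$values[cbind(r, cl)]
}

#' Per-patch covariate means from sampled pixels
#'
#' Samples a fraction of the patch's pixels (seed derived from the fire id
#' and day, so adding patches never reshuffles others) and returns the
#' mean of each covariate over the sampled pixel centers. Grids coarser
#' than the patch raster are sampled by nearest-cell lookup.
#'
#' @param patch a [DOBPatch-class]
#' @param grids named list of "covariateGrid" objects (or bare matrices on
#'   the same spec as \code{spec})
#' @param spec the patch raster's [GridSpec-class]
#' @param fraction sampling fraction (default 0.001)
#' @param seed integer base seed
#' @return Named numeric vector of covariate means.
#' @export
patchCovariateMeans <- function(patch, grids, spec, fraction = 0.001,
                                seed = 1) {
  if (!length(grids) || is.null(names(grids)) || any(names(grids) == ""))
    stop("grids must be a non-empty named list")
  sub <- samplePixels(patch@pixels, fraction,
                      seed = deriveSeed(seed, patch@fireId, patch@day))
  ctr <- cellCenters(spec, sub)
  vapply(grids, function(g) {
    if (is.matrix(g)) g <- covariateGrid(g, spec)
    mean(covariateAt(g, ctr[, 1], ctr[, 2]))
  }, numeric(1))
}

#' Monthly climate z-score
#'
#' Standardizes a fire-month climate value against a reference
#' distribution (the pooled April-June monthly values of a 30-year
#' reference period, e.g. 1986-2015): z = (value - mean(ref)) / sd(ref),
#' with the n-1 denominator for the standard deviation.
#'
#' @param value the fire ignition month's value
#' @param refValues numeric vector of reference monthly values (length >=
#'   2, nonzero variance)
#' @return List with z, refMean, refSd.
#' @export
monthlyZ <- function(value, refValues) {
  if (length(refValues) < 2) stop("need at least 2 reference values")
  m <- mean(refValues)
  s <- stats::sd(refValues)
  if (s == 0) stop("reference values have zero variance")
  list(z = (value - m) / s, refMean = m, refSd = s)
}

#' Circular transform of terrain aspect to eastness and northness
#'
#' eastness = sin(aspect), northness = cos(aspect) for aspect in degrees
#' clockwise from north; flat cells (NA aspect) get (0, 0) by convention.
#'
#' @param aspectDeg aspect in degrees, [0, 360); NA for flat cells
#' @return Two-column matrix (eastness, northness).
#' @export
#' @examples
#' aspectTransform(c(0, 90, 225))
aspectTransform <- function(aspectDeg) {
  if (any(aspectDeg < 0 | aspectDeg >= 360, na.rm = TRUE))
    stop("aspect must lie in [0, 360)")
  rad <- aspectDeg * pi / 180
  e <- sin(rad); n <- cos(rad)
  e[is.na(aspectDeg)] <- 0
  n[is.na(aspectDeg)] <- 0
  cbind(eastness = e, northness = n)
}
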