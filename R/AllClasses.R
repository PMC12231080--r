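#' @import methods
NULL

#' The coarse cover-type vocabulary
#'
#' The eleven coarse vegetation groups used throughout the package: ten
#' groups collapsed from a fine existing-vegetation-type legend (aspen,
#' cool conifer, disturbed, herbaceous, mixed aspen-conifer, nonflammable,
#' shrub, warm conifer, wetland, woodland) plus \code{prior_burn}, the
#' overlay class for area burned 1-10 years before a focal fire.
#'
#' @return Character vector of the 11 group names, in canonical order.
#'   Integer class codes used in [LandcoverGrid] rasters index this vector.
#' @export
#' @examples
#' coverTypes()
coverTypes <- function() {
  c("aspen", "cool_conifer", "disturbed", "herbaceous",
    "mixed_aspen_conifer", "nonflammable", "prior_burn", "shrub",
    "warm_conifer", "wetland", "woodland")
}

#' GridSpec: geometry of a planar raster grid
#'
#' Describes a regular planar grid in metric coordinates. Pixel (1,1) is the
#' top-left cell; x increases with column, y decreases with row (map
#' convention). The cell center of row i, column j is at
#' (originX + (j - 0.5) * pixelSize, originY - (i - 0.5) * pixelSize),
#' where (originX, originY) is the outer corner of the top-left pixel.
#'
#' @slot nRows,nCols integer, grid dimensions (>= 1)
#' @slot pixelSize numeric, cell edge length in meters (> 0); default 30
#' @slot originX,originY numeric, planar coordinates of the top-left
#'   pixel's outer (upper-left) corner
#' @export
setClass("GridSpec",
  representation(nRows = "integer", nCols = "integer", pixelSize = "numeric",
                 originX = "numeric", originY = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@nRows) != 1L || object@nRows < 1L)
      msg <- c(msg, "nRows must be a single integer >= 1")
    if (length(object@nCols) != 1L || object@nCols < 1L)
      msg <- c(msg, "nCols must be a single integer >= 1")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Create a GridSpec
#'
#' @param nRows,nCols grid dimensions
#' @param pixelSize cell size in meters (default 30, the native resolution
#'   of the landcover products the analysis is designed around)
#' @param originX,originY top-left outer-corner coordinates; by default the
#'   grid spans x in [0, nCols * pixelSize] and y in [0, nRows * pixelSize]
#' @return A [GridSpec-class] object.
#' @export
#' @examples
#' GridSpec(100, 100)
GridSpec <- function(nRows, nCols, pixelSize = 30,
                     originX = 0, originY = nRows * pixelSize) {
  new("GridSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      pixelSize = as.numeric(pixelSize), originX = as.numeric(originX),
      originY = as.numeric(originY))
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells, %.6g m pixels, origin (%.6g, %.6g)\n",
              object@nRows, object@nCols, object@pixelSize,
              object@originX, object@originY))
})

#' @describeIn GridSpec-class number of cells
#' @param spec a GridSpec
#' @export
nCells <- function(spec) spec@nRows * spec@nCols

#' Cell-center coordinates for grid cells
#'
#' @param spec a [GridSpec-class]
#' @param idx linear (column-major) cell indices; defaults to all cells
#' @return A two-column matrix of x, y center coordinates in meters.
#' @export
cellCenters <- function(spec, idx = seq_len(nCells(spec))) {
  nr <- spec@nRows
  r <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L
  cbind(x = spec@originX + (cl - 0.5) * spec@pixelSize,
        y = spec@originY - (r - 0.5) * spec@pixelSize)
}

#' Map planar coordinates to linear cell indices
#'
#' Points outside the grid get NA.
#'
#' @param spec a [GridSpec-class]
#' @param x,y coordinate vectors in meters
#' @return Integer vector of column-major cell indices.
#' @export
cellIndexAt <- function(spec, x, y) {
  cl <- floor((x - spec@originX) / spec@pixelSize) + 1
  r <- floor((spec@originY - y) / spec@pixelSize) + 1
  bad <- cl < 1 | cl > spec@nCols | r < 1 | r > spec@nRows
  out <- (cl - 1) * spec@nRows + r
  out[bad] <- NA
  as.integer(out)
}

#' LandcoverGrid: categorical cover-type raster
#'
#' A matrix-backed categorical raster over the 11-group cover vocabulary
#' (see [coverTypes()]). Cell values are integer codes indexing
#' \code{coverTypes()}; NA marks nodata.
#'
#' @slot spec a [GridSpec-class]
#' @slot classes integer matrix (nRows x nCols) of codes in 1..11, NA nodata
#' @export
setClass("LandcoverGrid",
  representation(spec = "GridSpec", classes = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@classes) == c(object@spec@nRows, object@spec@nCols)))
      msg <- c(msg, "classes dimensions must match spec")
    v <- object@classes[!is.na(object@classes)]
    if (length(v) && (any(v < 1L) || any(v > length(coverTypes()))))
      msg <- c(msg, "class codes must index the 11-group vocabulary")
    if (length(msg)) msg else TRUE
  })

#' Create a LandcoverGrid
#'
#' @param spec a [GridSpec-class]
#' @param classes matrix of integer codes (1..11) or cover-type names
#' @return A [LandcoverGrid-class].
#' @export
LandcoverGrid <- function(spec, classes) {
  if (is.character(classes)) {
    codes <- match(classes, coverTypes())
    if (any(is.na(codes) & !is.na(classes)))
      stop("unknown cover-type name(s): ",
           paste(unique(classes[is.na(codes) & !is.na(classes)]), collapse = ", "))
    classes <- matrix(as.integer(codes), spec@nRows, spec@nCols)
  }
  storage.mode(classes) <- "integer"
  new("LandcoverGrid", spec = spec, classes = classes)
}

setMethod("show", "LandcoverGrid", function(object) {
  tb <- table(factor(coverTypes()[object@classes], levels = coverTypes()))
  cat("LandcoverGrid on "); show(object@spec)
  pres <- tb[tb > 0]
  cat("  classes present:",
      paste(sprintf("%s (%.1f%%)", names(pres), 100 * pres / sum(tb)),
            collapse = ", "), "\n")
})

#' @describeIn LandcoverGrid-class the underlying integer code matrix
#' @param x a LandcoverGrid
#' @export
classMatrix <- function(x) x@classes

#' @describeIn LandcoverGrid-class cover-type name per cell (matrix)
#' @export
classNames <- function(x) {
  m <- matrix(coverTypes()[x@classes], nrow(x@classes), ncol(x@classes))
  m
}

#' @describeIn LandcoverGrid-class the grid geometry
#' @export
gridSpec <- function(x) x@spec

#' DOBGrid: per-pixel day of burning
#'
#' Integer day index for every burned pixel, NA elsewhere. Day indices are
#' >= 1; for interpolated grids the non-NA support equals the rasterized
#' interior of the fire perimeter.
#'
#' @slot spec a [GridSpec-class]
#' @slot day integer matrix of day indices, NA nodata
#' @export
setClass("DOBGrid",
  representation(spec = "GridSpec", day = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@day) == c(object@spec@nRows, object@spec@nCols)))
      msg <- c(msg, "day dimensions must match spec")
    v <- object@day[!is.na(object@day)]
    if (length(v) && any(v < 1L)) msg <- c(msg, "day values must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Create a DOBGrid
#' @param spec a [GridSpec-class]
#' @param day integer matrix of day-of-burning values (NA = unburned)
#' @return A [DOBGrid-class].
#' @export
DOBGrid <- function(spec, day) {
  storage.mode(day) <- "integer"
  new("DOBGrid", spec = spec, day = day)
}

setMethod("show", "DOBGrid", function(object) {
  v <- object@day[!is.na(object@day)]
  cat("DOBGrid on "); show(object@spec)
  if (length(v))
    cat(sprintf("  %d burned cells, days %d..%d\n", length(v), min(v), max(v)))
  else cat("  no burned cells\n")
})

#' @describeIn DOBGrid-class the day matrix
#' @param x a DOBGrid
#' @export
dayMatrix <- function(x) x@day

#' SpreadParams: cellular-automaton fire-spread parameters
#'
#' Per-day, per-neighbor ignition model: an unburned cell 8-adjacent to a
#' burned cell ignites with probability
#' \code{baseSpreadProb * perTypeMultiplier[type] * exp(weatherCoupling *
#' (w_t - mean(w)))}, clipped to [0, 1]. The multiplier encodes relative
#' flammability of each cover type; aspen defaults to 0.3 (the assumed
#' spread penalty the analysis pipeline must recover), nonflammable to 0,
#' conifer types to 1.
#'
#' @slot baseSpreadProb probability in (0,1)
#' @slot perTypeMultiplier named numeric over [coverTypes()], each in [0,1]
#' @slot weatherCoupling coefficient scaling spread by a daily weather index
#' @slot windStrength anisotropy coefficient (>= 0); 0 gives isotropic
#'   spread, larger values concentrate spread on downwind faces via the
#'   factor exp(windStrength * (cos(theta - wind_t) - 1)), where theta is
#'   the outward spread direction at a cell
#' @slot subStepsPerDay number of contact-process sub-steps per simulated
#'   day (>= 1). One day of real fire growth spans many 30-m cells; with
#'   the default 1 the front advances at most one cell per day, while
#'   larger values let a day's burn form a band several cells deep, the
#'   scale relation daily fire mapping assumes
#' @slot maxDays maximum number of simulated days
#' @slot rngSeed integer seed for the simulation's random stream
#' @export
setClass("SpreadParams",
  representation(baseSpreadProb = "numeric", perTypeMultiplier = "numeric",
                 weatherCoupling = "numeric", windStrength = "numeric",
                 subStepsPerDay = "integer",
                 maxDays = "integer", rngSeed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@baseSpreadProb <= 0 || object@baseSpreadProb >= 1)
      msg <- c(msg, "baseSpreadProb must lie in (0, 1)")
    m <- object@perTypeMultiplier
    if (!setequal(names(m), coverTypes()))
      msg <- c(msg, "perTypeMultiplier must be named over all 11 cover types")
    if (any(m < 0 | m > 1)) msg <- c(msg, "multipliers must lie in [0, 1]")
    if (object@windStrength < 0) msg <- c(msg, "windStrength must be >= 0")
    if (object@subStepsPerDay < 1L)
      msg <- c(msg, "subStepsPerDay must be >= 1")
    if (object@maxDays < 1L) msg <- c(msg, "maxDays must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Create SpreadParams
#'
#' Default multipliers follow relative flammability expectations for the
#' cover groups: conifer forests most fire-prone (1.0), woodland and shrub
#' intermediate, aspen strongly penalized (0.3), wetland likewise moist
#' (0.3), recent prior burns fuel-limited (0.2), nonflammable inert (0).
#'
#' @param baseSpreadProb per-neighbor per-day ignition probability (default
#'   0.2, which sustains spread through conifer but makes pure aspen
#'   marginal under 8-connectivity)
#' @param perTypeMultiplier named numeric; entries override the defaults
#' @param weatherCoupling daily-weather coefficient (default 0, no coupling)
#' @param windStrength spread anisotropy (default 0, isotropic)
#' @param subStepsPerDay spread sub-steps per day (default 1)
#' @param maxDays maximum simulated days (default 30)
#' @param rngSeed integer seed (default 1)
#' @param ... named per-type multiplier overrides, e.g. \code{aspen = 0}
#' @return A [SpreadParams-class].
#' @export
#' @examples
#' SpreadParams(aspen = 0.3)
SpreadParams <- function(baseSpreadProb = 0.2, perTypeMultiplier = numeric(),
                         weatherCoupling = 0, windStrength = 0,
                         subStepsPerDay = 1, maxDays = 30, rngSeed = 1,
                         ...) {
  mult <- c(aspen = 0.3, cool_conifer = 1, disturbed = 0.5, herbaceous = 0.9,
            mixed_aspen_conifer = 0.6, nonflammable = 0, prior_burn = 0.2,
            shrub = 0.8, warm_conifer = 1, wetland = 0.3, woodland = 0.7)
  override <- c(perTypeMultiplier, unlist(list(...)))
  if (length(override)) {
    bad <- setdiff(names(override), coverTypes())
    if (length(bad)) stop("unknown cover type(s): ", paste(bad, collapse = ", "))
    mult[names(override)] <- override
  }
  new("SpreadParams", baseSpreadProb = as.numeric(baseSpreadProb),
      perTypeMultiplier = mult[coverTypes()],
      weatherCoupling = as.numeric(weatherCoupling),
      windStrength = as.numeric(windStrength),
      subStepsPerDay = as.integer(subStepsPerDay),
      maxDays = as.integer(maxDays), rngSeed = as.integer(rngSeed))
}

setMethod("show", "SpreadParams", function(object) {
  cat(sprintf("SpreadParams: base %.3g, weather coupling %.3g, maxDays %d\n",
              object@baseSpreadProb, object@weatherCoupling, object@maxDays))
  m <- object@perTypeMultiplier
  cat("  multipliers:", paste(sprintf("%s=%.2g", names(m), m), collapse = " "),
      "\n")
})

#' FireEvent: one fire's perimeter, detections, and (optionally) truth
#'
#' @slot fireId character identifier
#' @slot ignitionDate a Date (calendar anchor for day index 1)
#' @slot perimeter list of closed rings; each ring is an n x 2 matrix of
#'   planar x, y vertices with first row equal to last. Rings are
#'   interpreted jointly under the even-odd rule, so interior holes
#'   (unburned islands) are simply additional rings.
#' @slot detections data.frame with columns x, y, day, sensor
#' @slot trueDob a [DOBGrid-class] with simulator ground truth, or NULL
#' @export
setClass("FireEvent",
  representation(fireId = "character", ignitionDate = "Date",
                 perimeter = "list", detections = "data.frame",
                 trueDob = "ANY"),
  validity = function(object) {
    msg <- character()
    if (length(object@perimeter) == 0)
      msg <- c(msg, "perimeter must contain at least one ring")
    for (rg in object@perimeter) {
      if (!is.matrix(rg) || ncol(rg) != 2 || nrow(rg) < 4)
        msg <- c(msg, "each ring must be an n x 2 matrix with n >= 4")
    }
    d <- object@detections
    need <- c("x", "y", "day")
    if (!all(need %in% names(d)))
      msg <- c(msg, "detections must have columns x, y, day")
    else if (nrow(d)) {
      if (any(d$day < 1)) msg <- c(msg, "detection days must be >= 1")
      bb <- perimeterBBox(object@perimeter)
      if (any(d$x < bb[1] | d$x > bb[3] | d$y < bb[2] | d$y > bb[4]))
        msg <- c(msg, "detections must fall inside the perimeter bounding box")
    }
    if (length(msg)) msg else TRUE
  })

#' Create a FireEvent
#'
#' @param fireId identifier
#' @param perimeter list of closed rings (n x 2 coordinate matrices)
#' @param detections data.frame with x, y, day (and optionally sensor)
#' @param ignitionDate calendar date of day index 1
#' @param trueDob optional [DOBGrid-class] ground truth
#' @return A [FireEvent-class].
#' @export
FireEvent <- function(fireId, perimeter, detections = emptyDetections(),
                      ignitionDate = as.Date("2000-01-01"), trueDob = NULL) {
  if (!"sensor" %in% names(detections) && nrow(detections))
    detections$sensor <- "unknown"
  new("FireEvent", fireId = as.character(fireId), perimeter = perimeter,
      detections = detections, ignitionDate = as.Date(ignitionDate),
      trueDob = trueDob)
}

#' An empty detections table
#' @return Zero-row data.frame with columns x, y, day, sensor.
#' @export
emptyDetections <- function() {
  data.frame(x = numeric(0), y = numeric(0), day = integer(0),
             sensor = character(0), stringsAsFactors = FALSE)
}

setMethod("show", "FireEvent", function(object) {
  cat(sprintf("FireEvent '%s': %d perimeter ring(s), %d detection(s)%s\n",
              object@fireId, length(object@perimeter), nrow(object@detections),
              if (!is.null(object@trueDob)) ", with ground-truth DOB" else ""))
})

#' @describeIn FireEvent-class the detections table
#' @param fire a FireEvent
#' @export
detections <- function(fire) fire@detections

#' @describeIn FireEvent-class the perimeter ring list
#' @export
perimeterRings <- function(fire) fire@perimeter

#' Bounding box of a ring list
#' @param rings list of n x 2 coordinate matrices
#' @return numeric c(xmin, ymin, xmax, ymax)
#' @export
perimeterBBox <- function(rings) {
  xs <- unlist(lapply(rings, function(r) r[, 1]))
  ys <- unlist(lapply(rings, function(r) r[, 2]))
  c(min(xs), min(ys), max(xs), max(ys))
}
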