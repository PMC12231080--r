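# Day-of-burning interpolation from dated detections, and the
# fire-inclusion filters.

#' Interpolate per-pixel day of burning from dated detections
#'
#' Assigns to every pixel whose center falls inside the fire perimeter the
#' day of its nearest detection (Euclidean distance, point to cell
#' center); exact distance ties resolve to the earlier day. Detections
#' outside the perimeter still participate in the interpolation but
#' generate no pixels of their own. Output day values are therefore always
#' among the days present in the detections.
#'
#' @param fire a [FireEvent-class] with at least one detection
#' @param spec the [GridSpec-class] of the output raster
#' @return A [DOBGrid-class]; NA outside the rasterized perimeter.
#' @export
interpolateDOB <- function(fire, spec) {
  det <- fire@detections
  if (!nrow(det)) stop("fire has zero detections")
  ctr <- cellCenters(spec)
  inside <- which(pointsInRings(ctr[, 1], ctr[, 2], fire@perimeter))
  day <- matrix(NA_integer_, spec@nRows, spec@nCols)
  if (length(inside)) {
    # detections sorted by ascending day: with first-hit tie-breaking the
    # earlier day wins on exact distance ties, and the result is invariant
    # to the original detection order
    o <- order(det$day)
    dx <- det$x[o]; dy <- det$y[o]; dd <- as.integer(det$day[o])
    cx <- ctr[inside, 1]; cy <- ctr[inside, 2]
    best <- rep(Inf, length(inside))
    bestDay <- rep(NA_integer_, length(inside))
    # blockwise squared-distance computation; blocks are processed in
    # ascending-day order and updates require a strict improvement, so the
    # earlier day wins exact ties
    blk <- max(1L, min(length(dx), floor(4e6 / max(1, length(inside)))))
    for (b in seq(1L, length(dx), by = blk)) {
      j <- b:min(b + blk - 1L, length(dx))
      d2 <- outer(cx, dx[j], "-")^2 + outer(cy, dy[j], "-")^2
      w <- max.col(-d2, ties.method = "first")
      bd <- d2[cbind(seq_along(w), w)]
      upd <- bd < best
      best[upd] <- bd[upd]
      bestDay[upd] <- dd[j][w[upd]]
    }
    day[inside] <- bestDay
  }
  DOBGrid(spec, day)
}

#' Apply the fire-inclusion filters
#'
#' A fire enters the spread analysis only if it has at least
#' \code{minDetections} detections and the aspen cover type occupies at
#' least \code{minAspenFraction} of the rasterized perimeter interior
#' (defaults: 10 detections, 0.001 i.e. 0.1 percent aspen). Both bounds
#' are inclusive.
#'
#' @param fire a [FireEvent-class]
#' @param landcover a [LandcoverGrid-class] covering the perimeter
#' @param minDetections minimum detection count (default 10)
#' @param minAspenFraction minimum aspen proportion within the perimeter
#'   (default 0.001)
#' @return List with \code{pass} (logical) and \code{reasons} (character
#'   vector naming each failed filter: "detections", "aspen").
#' @export
passesInclusionFilters <- function(fire, landcover, minDetections = 10,
                                   minAspenFraction = 0.001) {
  reasons <- character()
  if (nrow(fire@detections) < minDetections) reasons <- c(reasons, "detections")
  ctr <- cellCenters(landcover@spec)
  inside <- which(pointsInRings(ctr[, 1], ctr[, 2], fire@perimeter))
  aspen <- if (length(inside)) {
    cp <- coverProportions(landcover, inside)
    cp$proportions[["aspen"]]
  } else 0
  if (aspen < minAspenFraction) reasons <- c(reasons, "aspen")
  list(pass = length(reasons) == 0L, reasons = reasons)
}
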