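# Daily DOB patches and the two spread metrics: daily area burned and
# maximum daily linear spread.

#' DOBPatch: one day's spatially discrete burn patch
#'
#' A single connected component (8-connectivity) of pixels that burned on
#' the same day; the unit of the spread analysis.
#'
#' @slot fireId character
#' @slot day integer day index
#' @slot pixels integer vector of linear (column-major) cell indices
#' @slot areaHa patch area in hectares
#' @slot maxLinearSpreadM maximum linear spread in meters (NA until
#'   computed)
#' @slot discontinuous TRUE when the patch shares no boundary with any
#'   earlier-day burn (first-day patches and spot fires)
#' @slot coverage named numeric of cover-type proportions (may be empty)
#' @slot covariates named numeric of covariate means (may be empty)
#' @export
setClass("DOBPatch",
  representation(fireId = "character", day = "integer", pixels = "integer",
                 areaHa = "numeric", maxLinearSpreadM = "numeric",
                 discontinuous = "logical", coverage = "numeric",
                 covariates = "numeric"),
  validity = function(object) {
    if (!length(object@pixels)) return("patch must contain pixels")
    TRUE
  })

setMethod("show", "DOBPatch", function(object) {
  cat(sprintf(
    "DOBPatch %s day %d: %d px, %.2f ha, spread %.1f m%s\n",
    object@fireId, object@day, length(object@pixels), object@areaHa,
    object@maxLinearSpreadM,
    if (isTRUE(object@discontinuous)) " (discontinuous)" else ""))
})

# connected-component labels (8-connectivity) for a set of linear indices
labelComponents8 <- function(idx, nr, nc) {
  pos <- integer(nr * nc)
  pos[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L
  from <- integer(0); to <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- cl + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- pos[(c2[ok] - 1L) * nr + r2[ok]]
    keep <- nb > 0L
    from <- c(from, which(ok)[keep]); to <- c(to, nb[keep])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  igraph::components(g)$membership
}

# TRUE for pixels of `idx` that are 8-adjacent to any pixel in `other`
adjacentToSet <- function(idx, other, nr, nc) {
  inOther <- logical(nr * nc)
  inOther[other] <- TRUE
  r <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L
  hit <- logical(length(idx))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    r2 <- r + dr; c2 <- cl + dc
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    hit[ok] <- hit[ok] | inOther[(c2[ok] - 1L) * nr + r2[ok]]
  }
  hit
}

#' Decompose a DOB grid into daily patches
#'
#' For each day value present in the grid, the 8-connected components of
#' that day's pixels become separate patches; every burned pixel belongs to
#' exactly one patch. Patch areas are filled in; spread metrics are
#' computed by [computeSpreadMetrics()].
#'
#' @param dob a [DOBGrid-class]
#' @param fireId identifier stamped on the patches
#' @return List of [DOBPatch-class] objects, ordered by day.
#' @export
extractPatches <- function(dob, fireId = "fire") {
  spec <- dob@spec
  d <- dob@day
  if (all(is.na(d))) stop("DOB grid is empty")
  out <- list()
  for (day in sort(unique(d[!is.na(d)]))) {
    idx <- which(!is.na(d) & d == day)
    memb <- labelComponents8(idx, spec@nRows, spec@nCols)
    for (m in seq_len(max(memb))) {
      px <- idx[memb == m]
      out[[length(out) + 1L]] <- new("DOBPatch",
        fireId = fireId, day = as.integer(day), pixels = as.integer(px),
        areaHa = dailyArea(length(px), spec@pixelSize),
        maxLinearSpreadM = NA_real_, discontinuous = NA,
        coverage = numeric(0), covariates = numeric(0))
    }
  }
  out
}

#' Shared boundary of a patch with the previous days' burn
#'
#' The subset of the patch's pixels that are 8-adjacent to any pixel
#' burned on an earlier day. An empty result marks the patch as
#' discontinuous (a first-day patch or one initiated by spot fire).
#'
#' @param patch a [DOBPatch-class]
#' @param priorFootprint integer vector of linear indices of pixels burned
#'   on earlier days
#' @param spec the [GridSpec-class]
#' @return Integer vector of shared-boundary pixel indices (possibly
#'   empty).
#' @export
sharedBoundary <- function(patch, priorFootprint, spec) {
  if (!length(priorFootprint)) return(integer(0))
  px <- patch@pixels
  px[adjacentToSet(px, priorFootprint, spec@nRows, spec@nCols)]
}

#' Maximum daily linear spread of a patch
#'
#' Continuous case (non-empty shared boundary): for every pixel of the
#' patch, the Euclidean distance from its center to the nearest
#' shared-boundary pixel center (exact distance transform); the maximum
#' over the patch is returned and represents the extent of that day's fire
#' progression. Discontinuous case: the distance is seeded at the earliest
#' detection of that day falling inside the patch (fallback: the patch
#' centroid) and the maximum seed-to-pixel-center distance is returned.
#'
#' @param patch a [DOBPatch-class]
#' @param shared integer vector of shared-boundary pixel indices (from
#'   [sharedBoundary()]); empty means discontinuous
#' @param detections detections data.frame (used only in the
#'   discontinuous case)
#' @param spec the [GridSpec-class]
#' @return Distance in meters.
#' @export
maxLinearSpread <- function(patch, shared, detections, spec) {
  px <- patch@pixels
  if (length(shared)) {
    r <- ((px - 1L) %% spec@nRows) + 1L
    cl <- ((px - 1L) %/% spec@nRows) + 1L
    r0 <- min(r); c0 <- min(cl)
    nr <- max(r) - r0 + 1L; nc <- max(cl) - c0 + 1L
    sr <- ((shared - 1L) %% spec@nRows) + 1L - r0 + 1L
    sc <- ((shared - 1L) %/% spec@nRows) + 1L - c0 + 1L
    D <- distanceTransform(nr, nc, (sc - 1L) * nr + sr)
    max(D[cbind(r - r0 + 1L, cl - c0 + 1L)]) * spec@pixelSize
  } else {
    ctr <- cellCenters(spec, px)
    seed <- patchSeedPoint(patch, detections, spec)
    max(sqrt((ctr[, 1] - seed[1])^2 + (ctr[, 2] - seed[2])^2))
  }
}

# seed point for a discontinuous patch: centroid of the earliest same-day
# detection falling inside the patch, else the patch centroid
patchSeedPoint <- function(patch, detections, spec) {
  ctr <- cellCenters(spec, patch@pixels)
  if (!is.null(detections) && nrow(detections)) {
    d <- detections[detections$day == patch@day, , drop = FALSE]
    if (nrow(d)) {
      cellIdx <- cellIndexAt(spec, d$x, d$y)
      inPatch <- !is.na(cellIdx) & cellIdx %in% patch@pixels
      d <- d[inPatch, , drop = FALSE]
      if (nrow(d)) {
        d <- d[order(d$day, d$x, d$y), , drop = FALSE]
        return(c(d$x[1], d$y[1]))
      }
    }
  }
  c(mean(ctr[, 1]), mean(ctr[, 2]))
}

#' Alternative spread statistic: closest non-shared boundary distance
#'
#' The minimum, over the patch's non-shared boundary pixels (pixels on the
#' patch's outer edge that are not part of the shared boundary), of the
#' distance to the nearest shared-boundary pixel center. This is the
#' "closest boundary" reading of daily linear spread; it is reported for
#' comparison but not used in the models.
#'
#' @inheritParams maxLinearSpread
#' @return Distance in meters, or NA for discontinuous patches or patches
#'   with no non-shared boundary pixels.
#' @export
closestBoundarySpread <- function(patch, shared, spec) {
  if (!length(shared)) return(NA_real_)
  px <- patch@pixels
  outside <- setdiff(seq_len(nCells(spec)), px)
  edge <- px[adjacentToSet(px, outside, spec@nRows, spec@nCols)]
  nonshared <- setdiff(edge, shared)
  if (!length(nonshared)) return(NA_real_)
  a <- cellCenters(spec, nonshared)
  b <- cellCenters(spec, shared)
  mind <- vapply(seq_len(nrow(a)), function(i)
    min(sqrt((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2)), numeric(1))
  min(mind)
}

#' Daily area burned of a patch
#'
#' @param nPixels pixel count of the patch
#' @param pixelSize cell edge length in meters
#' @return Area in hectares: nPixels * pixelSize^2 / 10000.
#' @export
#' @examples
#' dailyArea(100, 30)  # 9 ha
dailyArea <- function(nPixels, pixelSize) {
  nPixels * pixelSize^2 / 1e4
}

#' Compute spread metrics and cover proportions for all patches of a fire
#'
#' Fills in, for every patch: the discontinuity flag and maximum linear
#' spread (against the cumulative footprint of all earlier days), and
#' optionally cover-type proportions from a landcover grid.
#'
#' @param patches list of [DOBPatch-class] from [extractPatches()]
#' @param dob the [DOBGrid-class] the patches came from
#' @param detections detections data.frame (seeds discontinuous patches);
#'   may be NULL
#' @param landcover optional [LandcoverGrid-class] for per-patch cover
#'   proportions
#' @return The patch list with metrics filled in.
#' @export
computeSpreadMetrics <- function(patches, dob, detections = NULL,
                                 landcover = NULL) {
  spec <- dob@spec
  d <- dob@day
  lapply(patches, function(p) {
    prior <- which(!is.na(d) & d < p@day)
    sh <- sharedBoundary(p, prior, spec)
    p@discontinuous <- length(sh) == 0L
    p@maxLinearSpreadM <- maxLinearSpread(p, sh, detections, spec)
    if (!is.null(landcover))
      p@coverage <- coverProportions(landcover, p@pixels)$proportions
    p
  })
}

#' Patch list to a flat table
#'
#' @param patches list of [DOBPatch-class]
#' @return data.frame with fire_id, day, n_pixels, area_ha,
#'   max_linear_spread_m, discontinuous, one column per cover-type
#'   proportion present, and one per covariate mean present.
#' @export
patchTable <- function(patches) {
  base <- data.frame(
    fire_id = vapply(patches, function(p) p@fireId, character(1)),
    day = vapply(patches, function(p) p@day, integer(1)),
    n_pixels = vapply(patches, function(p) length(p@pixels), integer(1)),
    area_ha = vapply(patches, function(p) p@areaHa, numeric(1)),
    max_linear_spread_m = vapply(patches, function(p) p@maxLinearSpreadM,
                                 numeric(1)),
    discontinuous = vapply(patches, function(p) isTRUE(p@discontinuous),
                           logical(1)),
    stringsAsFactors = FALSE)
  covNames <- unique(unlist(lapply(patches, function(p) names(p@coverage))))
  for (nm in covNames)
    base[[nm]] <- vapply(patches, function(p)
      if (nm %in% names(p@coverage)) p@coverage[[nm]] else 0, numeric(1))
  covarNames <- unique(unlist(lapply(patches, function(p) names(p@covariates))))
  for (nm in covarNames)
    base[[nm]] <- vapply(patches, function(p)
      if (nm %in% names(p@covariates)) p@covariates[[nm]] else NA_real_,
      numeric(1))
  base
}
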