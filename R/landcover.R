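# Reclassification of fine vegetation legends into the 11 coarse groups,
# prior-burn overlays, and cover proportions over pixel sets.

#' Read a fine-code to coarse-group legend mapping
#'
#' The mapping file is a two-column CSV with header \code{fine_code,group};
#' every group must be one of [coverTypes()]. A stub legend with synthetic
#' fine codes ships with the package (see
#' \code{system.file("extdata", "evt_legend_stub_synthetic.csv",
#' package = "fireprogress")}); a real legend for a given landcover
#' product is supplied the same way.
#'
#' @param path CSV file path
#' @return Named integer-keyed mapping: a data.frame with columns
#'   \code{fine_code} (integer) and \code{group} (character).
#' @export
readLegend <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("fine_code", "group") %in% names(m)))
    stop("legend must have columns fine_code, group")
  bad <- setdiff(unique(m$group), coverTypes())
  if (length(bad))
    stop("legend maps to unknown group(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(m$fine_code))
    stop("legend contains duplicated fine codes")
  m$fine_code <- as.integer(m$fine_code)
  m
}

#' Reclassify a fine-legend raster into the coarse cover groups
#'
#' @param fineRaster integer matrix of fine vegetation codes (NA nodata)
#' @param mapping legend data.frame as returned by [readLegend()] (columns
#'   fine_code, group)
#' @param spec the [GridSpec-class] of the raster
#' @return A [LandcoverGrid-class]; nodata cells preserved.
#' @export
reclassify <- function(fineRaster, mapping, spec) {
  codes <- unique(fineRaster[!is.na(fineRaster)])
  missing <- setdiff(codes, mapping$fine_code)
  if (length(missing))
    stop("unmapped fine code(s): ", paste(sort(missing), collapse = ", "))
  grp <- mapping$group[match(fineRaster, mapping$fine_code)]
  out <- matrix(match(grp, coverTypes()), nrow(fineRaster), ncol(fineRaster))
  LandcoverGrid(spec, out)
}

#' Create a burn-history record set
#'
#' @param perimeters list of ring lists (one per historical fire)
#' @param years integer calendar years, one per fire
#' @return A list of records with elements \code{perimeter} and \code{year}.
#' @export
burnHistory <- function(perimeters, years) {
  if (length(perimeters) != length(years)) stop("length mismatch")
  if (any(years <= 0)) stop("years must be positive integers")
  mapply(function(p, y) list(perimeter = p, year = as.integer(y)),
         perimeters, years, SIMPLIFY = FALSE)
}

#' Overlay recent prior burns onto a landcover grid
#'
#' Cells whose centers fall inside a historical burn perimeter are
#' reclassified to \code{prior_burn} when the most recent burn covering
#' them occurred 1-10 years before the focal fire year; more recent burns
#' take precedence where perimeters overlap, and burns outside the window
#' (including same-year burns) leave cells unchanged.
#'
#' @param landcover a [LandcoverGrid-class]
#' @param history list of records from [burnHistory()]
#' @param fireYear focal fire calendar year
#' @param window integer c(min, max) years-since-burn window (default
#'   c(1, 10))
#' @return A new [LandcoverGrid-class].
#' @export
applyPriorBurns <- function(landcover, history, fireYear,
                            window = c(1L, 10L)) {
  spec <- landcover@spec
  ctr <- cellCenters(spec)
  lastYear <- rep(NA_integer_, nCells(spec))
  for (rec in history) {
    if (rec$year > fireYear) next
    bb <- perimeterBBox(rec$perimeter)
    cand <- which(ctr[, 1] >= bb[1] & ctr[, 1] <= bb[3] &
                  ctr[, 2] >= bb[2] & ctr[, 2] <= bb[4])
    if (!length(cand)) next
    inside <- pointsInRings(ctr[cand, 1], ctr[cand, 2], rec$perimeter)
    hit <- cand[inside]
    upd <- is.na(lastYear[hit]) | rec$year > lastYear[hit]
    lastYear[hit[upd]] <- rec$year
  }
  gap <- fireYear - lastYear
  toBurn <- !is.na(gap) & gap >= window[1] & gap <= window[2]
  cls <- landcover@classes
  toBurn <- toBurn & !is.na(cls)
  cls[toBurn] <- match("prior_burn", coverTypes())
  LandcoverGrid(spec, cls)
}

#' Cover-type proportions over a pixel set
#'
#' Proportions of each of the 11 coarse groups among the (non-nodata)
#' pixels of the given set; absent groups get 0 and the proportions sum
#' to 1.
#'
#' @param landcover a [LandcoverGrid-class]
#' @param pixels integer vector of linear (column-major) cell indices
#' @return Named list with \code{proportions} (named numeric over
#'   [coverTypes()]) and \code{nPixels} (count of non-nodata pixels used).
#' @export
coverProportions <- function(landcover, pixels) {
  if (!length(pixels)) stop("pixel set is empty")
  if (any(pixels < 1 | pixels > nCells(landcover@spec)))
    stop("pixel indices outside the grid")
  v <- landcover@classes[pixels]
  v <- v[!is.na(v)]
  if (!length(v)) stop("all pixels in the set are nodata")
  tb <- tabulate(v, nbins = length(coverTypes()))
  props <- tb / sum(tb)
  names(props) <- coverTypes()
  list(proportions = props, nPixels = length(v))
}

#' Pick the landcover version preceding a fire year
#'
#' Given the calendar years of available landcover map versions, selects
#' the most recent version strictly preceding the fire year (i.e. the
#' largest version year \code{<= fireYear - 1}), falling back to the
#' earliest version for fires that predate all maps.
#'
#' @param versionYears integer vector of available version years
#' @param fireYear focal fire year
#' @return The selected version year.
#' @export
landcoverVersionFor <- function(versionYears, fireYear) {
  ok <- versionYears[versionYears <= fireYear - 1]
  if (length(ok)) max(ok) else min(versionYears)
}
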