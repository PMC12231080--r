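# The Fire Perimeter Effect: perimeter vs. interior cover proportions,
# the FPE statistic, sign tests, and Bonferroni control.

#' Perimeter-band and interior pixel sets for a fire
#'
#' The perimeter set contains every cell whose center lies within
#' \code{halfWidth} meters of the perimeter polyline, on either side (the
#' default 60 m gives a 120-m band, i.e. up to two 30-m landcover pixels
#' on each side). The interior set contains cells inside the polygon at
#' distance greater than \code{halfWidth} from the boundary; with
#' \code{interior = "ring"} it is instead restricted to the 60-m-deep ring
#' just inside the band (depth halfWidth..2*halfWidth). The two sets are
#' always disjoint.
#'
#' @param perimeter list of closed rings (a fire perimeter, possibly with
#'   holes)
#' @param spec a [GridSpec-class]
#' @param halfWidth buffer half-width in meters (> 0, default 60)
#' @param interior "full" (everything deeper than the band; default) or
#'   "ring" (only the next halfWidth meters inward)
#' @return List with integer index vectors \code{perimeterSet} and
#'   \code{interiorSet}, and \code{emptyInterior} flagging fires too small
#'   to have an interior at this half-width.
#' @export
perimeterInteriorMasks <- function(perimeter, spec, halfWidth = 60,
                                   interior = c("full", "ring")) {
  interior <- match.arg(interior)
  if (halfWidth <= 0) stop("halfWidth must be > 0")
  ctr <- cellCenters(spec)
  bb <- perimeterBBox(perimeter)
  cand <- which(ctr[, 1] >= bb[1] - halfWidth & ctr[, 1] <= bb[3] + halfWidth &
                ctr[, 2] >= bb[2] - halfWidth & ctr[, 2] <= bb[4] + halfWidth)
  d <- distanceToBoundary(ctr[cand, 1], ctr[cand, 2], perimeter)
  inside <- pointsInRings(ctr[cand, 1], ctr[cand, 2], perimeter)
  perimSet <- cand[d <= halfWidth]
  intKeep <- if (interior == "full") {
    inside & d > halfWidth
  } else {
    inside & d > halfWidth & d <= 2 * halfWidth
  }
  interiorSet <- cand[intKeep]
  list(perimeterSet = perimSet, interiorSet = interiorSet,
       emptyInterior = length(interiorSet) == 0L)
}

#' The Fire Perimeter Effect statistic
#'
#' FPE = (P - I) / (P + I) for a cover type's perimeter proportion P and
#' interior proportion I. Constrained to [-1, 1]; positive values mean the
#' type is over-represented at the fire's edge (a barrier effect),
#' negative values that it is more common in the burn interior. The
#' statistic is scale independent: fpe(cP, cI) = fpe(P, I). Undefined
#' (NA) when P + I = 0.
#'
#' @param perimeterProp,interiorProp proportions in [0, 1] (vectorized)
#' @return Numeric FPE values in [-1, 1], NA where undefined.
#' @export
#' @examples
#' fpe(0.2, 0.1)  # a type twice as common at perimeters: 1/3
fpe <- function(perimeterProp, interiorProp) {
  if (any(perimeterProp < 0 | perimeterProp > 1 |
          interiorProp < 0 | interiorProp > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]")
  s <- perimeterProp + interiorProp
  ifelse(s > 0, (perimeterProp - interiorProp) / s, NA_real_)
}

#' Percent abundance excess implied by an FPE value
#'
#' Inverts the FPE formula: an FPE of f corresponds to a
#' perimeter:interior proportion ratio of (1 + f) / (1 - f), i.e. the
#' cover type is 100 * ((1 + f) / (1 - f) - 1) percent more abundant at
#' perimeters than in burn interiors.
#'
#' @param fpeValue FPE in (-1, 1)
#' @return Percent excess (vectorized).
#' @export
#' @examples
#' impliedAbundanceExcess(0.18)  # ~44 percent
#' impliedAbundanceExcess(1 / 3) # 100 percent: twice as common
impliedAbundanceExcess <- function(fpeValue) {
  if (any(abs(fpeValue) >= 1, na.rm = TRUE))
    stop("|fpe| must be < 1 (ratio is infinite at the boundary)")
  100 * ((1 + fpeValue) / (1 - fpeValue) - 1)
}

#' Exact two-sided sign test on FPE values
#'
#' Counts fires with positive and negative FPE for a cover type (NA and
#' exactly-zero values are excluded and reported) and evaluates the
#' two-sided exact binomial test at null success probability 0.5. The
#' two-sided p-value is the minimum-likelihood sum: the total probability
#' of outcomes no more likely than the observed count.
#'
#' @param fpeValues numeric FPE values, possibly containing NA
#' @param threshold significance threshold; default the Bonferroni-adjusted
#'   [bonferroniThreshold()] for 11 cover types
#' @return List with nPos, nNeg, nExcluded, pValue (NA when no nonzero
#'   values) and significant.
#' @export
signTest <- function(fpeValues, threshold = bonferroniThreshold()) {
  nPos <- sum(fpeValues > 0, na.rm = TRUE)
  nNeg <- sum(fpeValues < 0, na.rm = TRUE)
  nExcluded <- length(fpeValues) - nPos - nNeg
  p <- if (nPos + nNeg > 0)
    stats::binom.test(nPos, nPos + nNeg, p = 0.5)$p.value
  else NA_real_
  list(nPos = nPos, nNeg = nNeg, nExcluded = nExcluded, pValue = p,
       significant = !is.na(p) && p < threshold)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error rate (default 0.05)
#' @param k number of comparisons (default 11, one per cover type)
#' @return alpha / k (0.05 / 11 = 0.0045 at 4 decimals).
#' @export
bonferroniThreshold <- function(alpha = 0.05, k = 11) {
  if (k < 1) stop("k must be >= 1")
  alpha / k
}

#' Per-fire, per-type FPE table
#'
#' Computes perimeter and interior cover proportions for one fire and the
#' FPE of each of the 11 cover types.
#'
#' @param fire a [FireEvent-class]
#' @param landcover a [LandcoverGrid-class]
#' @param halfWidth buffer half-width in meters (default 60)
#' @param interior interior definition, see [perimeterInteriorMasks()]
#' @return data.frame with columns fire_id, group, perimeter_prop,
#'   interior_prop, fpe (NA where undefined or the interior is empty).
#' @export
fpeTable <- function(fire, landcover, halfWidth = 60,
                     interior = c("full", "ring")) {
  masks <- perimeterInteriorMasks(fire@perimeter, landcover@spec,
                                  halfWidth, interior)
  pp <- coverProportions(landcover, masks$perimeterSet)$proportions
  if (!masks$emptyInterior) {
    ip <- coverProportions(landcover, masks$interiorSet)$proportions
    f <- fpe(pp, ip)
  } else {
    ip <- rep(NA_real_, length(pp))
    f <- rep(NA_real_, length(pp))
  }
  data.frame(fire_id = fire@fireId, group = coverTypes(),
             perimeter_prop = as.numeric(pp), interior_prop = as.numeric(ip),
             fpe = as.numeric(f), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Sign-test summary across fires, per cover type
#'
#' @param fpeTables data.frame of stacked [fpeTable()] rows across fires
#' @param alpha family-wise error rate (default 0.05)
#' @return data.frame with one row per cover type: counts, exact binomial
#'   p-value and significance at the Bonferroni threshold alpha / 11.
#' @export
signTestByGroup <- function(fpeTables, alpha = 0.05) {
  groups <- coverTypes()
  thr <- bonferroniThreshold(alpha, length(groups))
  rows <- lapply(groups, function(g) {
    st <- signTest(fpeTables$fpe[fpeTables$group == g], threshold = thr)
    data.frame(group = g, n_pos = st$nPos, n_neg = st$nNeg,
               n_excluded = st$nExcluded, p_value = st$pValue,
               significant = st$significant, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- thr
  out
}
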