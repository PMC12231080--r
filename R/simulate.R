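# Cellular-automaton fire spread and synthetic satellite detections.

#' Simulate a fire as a stochastic contact process on a landcover grid
#'
#' Daily cellular automaton with 8-connectivity: the ignition cell burns on
#' day 1; on each subsequent day every unburned cell adjacent to a burned
#' cell ignites with probability \code{baseSpreadProb *
#' perTypeMultiplier[type] * exp(weatherCoupling * (w_t - mean(w)))},
#' clipped to [0, 1]. The simulation stops at \code{maxDays} or when no
#' ignitable cell remains adjacent to the burn (fuel exhaustion); days on
#' which no cell happens to ignite are quiet smoldering days, not the end
#' of the fire, and simply contribute no burned cells (so they are absent
#' from the day-of-burning record, like real discontinuous progressions).
#' The final perimeter is the traced
#' boundary of the burned footprint (unburned islands become holes), and
#' per-cell ignition days are kept as ground truth.
#'
#' @param landcover a [LandcoverGrid-class]
#' @param ignition integer c(row, col) of the ignition cell, which must be
#'   flammable (multiplier > 0)
#' @param params a [SpreadParams-class]
#' @param dailyWeather numeric vector of a daily weather index, at least
#'   \code{maxDays} long; default constant (no weather forcing)
#' @param fireId identifier stamped on the result (also folded into the
#'   random stream, making fires independent of each other)
#' @param dailyWindDir optional vector of daily wind (spread) directions
#'   in degrees (0 = +x, counter-clockwise); used only when
#'   \code{params@windStrength > 0}, concentrating each day's spread on
#'   the downwind sector of the fire front so fires make directional runs
#' @return A [FireEvent-class] with perimeter, empty detections, and
#'   \code{trueDob} ground truth.
#' @export
simulateFire <- function(landcover, ignition, params,
                         dailyWeather = rep(0, params@maxDays),
                         fireId = "fire_1", dailyWindDir = NULL) {
  spec <- landcover@spec
  cls <- landcover@classes
  if (all(is.na(cls))) stop("landscape is empty (all nodata)")
  if (length(dailyWeather) < params@maxDays)
    stop("dailyWeather must supply at least maxDays values")
  useWind <- params@windStrength > 0 && !is.null(dailyWindDir)
  if (useWind && length(dailyWindDir) < params@maxDays)
    stop("dailyWindDir must supply at least maxDays values")
  mult <- params@perTypeMultiplier[coverTypes()]
  multGrid <- matrix(0, spec@nRows, spec@nCols)
  ok <- !is.na(cls)
  multGrid[ok] <- mult[cls[ok]]
  ig <- as.integer(ignition)
  if (length(ig) != 2 || ig[1] < 1 || ig[1] > spec@nRows ||
      ig[2] < 1 || ig[2] > spec@nCols)
    stop("ignition must be a valid c(row, col)")
  if (multGrid[ig[1], ig[2]] <= 0)
    stop("ignition cell is not flammable (multiplier <= 0)")
  set.seed(deriveSeed(params@rngSeed, fireId, "spread"))
  nr <- spec@nRows; nc <- spec@nCols
  dob <- matrix(NA_integer_, nr, nc)
  dob[ig[1], ig[2]] <- 1L
  wbar <- mean(dailyWeather[seq_len(params@maxDays)])
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), , drop = FALSE]
  # exposed: unburned flammable cells 8-adjacent to the burn; maintained
  # incrementally as new cells ignite
  exposed <- matrix(FALSE, nr, nc)
  expose <- function(cells) {
    for (k in seq_len(nrow(offs))) {
      rr <- cells[, 1] + offs[k, 1]
      cc <- cells[, 2] + offs[k, 2]
      keep <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- cbind(rr[keep], cc[keep])
      if (!nrow(nb)) next
      open <- is.na(dob[nb]) & multGrid[nb] > 0
      exposed[nb[open, , drop = FALSE]] <<- TRUE
    }
  }
  expose(matrix(ig, 1, 2))
  out <- FALSE
  for (day in seq(2L, length.out = max(0L, params@maxDays - 1L))) {
    if (out) break
    for (step in seq_len(params@subStepsPerDay)) {
    cand <- which(exposed, arr.ind = TRUE)
    if (!nrow(cand)) { out <- TRUE; break }
    wf <- exp(params@weatherCoupling * (dailyWeather[day] - wbar))
    dirf <- 1
    if (useWind) {
      # outward spread direction at each candidate: mean offset away from
      # its burned 8-neighbors (x = +col, y = -row in planar terms)
      ox <- numeric(nrow(cand)); oy <- numeric(nrow(cand))
      for (k in seq_len(nrow(offs))) {
        rr <- cand[, 1] + offs[k, 1]
        cc <- cand[, 2] + offs[k, 2]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        b <- logical(nrow(cand))
        b[ok] <- !is.na(dob[cbind(rr[ok], cc[ok])])
        ox[b] <- ox[b] - offs[k, 2]
        oy[b] <- oy[b] + offs[k, 1]
      }
      nrm <- sqrt(ox^2 + oy^2)
      nrm[nrm == 0] <- 1
      th <- dailyWindDir[day] * pi / 180
      cosang <- (ox * cos(th) + oy * sin(th)) / nrm
      dirf <- exp(params@windStrength * (cosang - 1))
    }
    p <- pmin(1, pmax(0, params@baseSpreadProb * multGrid[cand] * wf * dirf))
    lit <- stats::runif(nrow(cand)) < p
    if (!any(lit)) next  # a quiet (smoldering) step; the fire is not out
    newCells <- cand[lit, , drop = FALSE]
    dob[newCells] <- day
    exposed[newCells] <- FALSE
    expose(newCells)
    }
  }
  burned <- !is.na(dob)
  rings <- maskToRings(burned, spec)
  FireEvent(fireId = fireId, perimeter = rings,
            trueDob = DOBGrid(spec, dob))
}

#' Thin and jitter ground-truth burn days into synthetic fire detections
#'
#' Emulates sparse satellite active-fire detections: for each burn day,
#' each newly burned cell is retained independently with probability
#' \code{rate / 100} (so \code{rate} is the expected number of detections
#' per 100 burned cells per day), and a detection is placed at the
#' retained cell's center plus isotropic Gaussian positional jitter. The
#' detection day is the true burn day. Jittered detections are clamped to
#' the perimeter bounding box implied by the burned cells.
#'
#' @param trueDob a [DOBGrid-class] of per-cell burn days
#' @param rate expected detections per 100 burned cells per day (> 0)
#' @param jitterSigma positional jitter standard deviation in meters per
#'   axis (>= 0)
#' @param seed integer seed
#' @param minPerDay minimum detections per burning day (default 0, pure
#'   thinning). A positive floor emulates daily satellite revisits that
#'   always register an active front regardless of how little area burned
#'   that day; floor detections are drawn uniformly from the day's cells.
#' @return Detections data.frame (x, y, day, sensor), possibly empty.
#' @export
sampleDetections <- function(trueDob, rate, jitterSigma = 0, seed = 1,
                             minPerDay = 0) {
  if (rate <= 0) stop("rate must be > 0")
  dob <- trueDob@day
  idx <- which(!is.na(dob))
  if (!length(idx)) return(emptyDetections())
  set.seed(deriveSeed(seed, "detections"))
  keep <- stats::runif(length(idx)) < min(1, rate / 100)
  if (minPerDay > 0) {
    for (day in sort(unique(dob[idx]))) {
      dayPos <- which(dob[idx] == day)
      short <- minPerDay - sum(keep[dayPos])
      if (short > 0) {
        pool <- dayPos[!keep[dayPos]]
        add <- if (length(pool) <= short) pool
          else pool[sample.int(length(pool), short)]
        keep[add] <- TRUE
      }
    }
  }
  idx <- idx[keep]
  if (!length(idx)) return(emptyDetections())
  ctr <- cellCenters(trueDob@spec, idx)
  x <- ctr[, 1]; y <- ctr[, 2]
  if (jitterSigma > 0) {
    x <- x + stats::rnorm(length(idx), sd = jitterSigma)
    y <- y + stats::rnorm(length(idx), sd = jitterSigma)
  }
  # keep jittered points inside the burned footprint's bounding box so the
  # FireEvent bounding-box invariant holds
  allc <- cellCenters(trueDob@spec, which(!is.na(dob)))
  px <- trueDob@spec@pixelSize
  x <- pmin(max(allc[, 1]) + px / 2, pmax(min(allc[, 1]) - px / 2, x))
  y <- pmin(max(allc[, 2]) + px / 2, pmax(min(allc[, 2]) - px / 2, y))
  d <- data.frame(x = x, y = y, day = as.integer(dob[idx]),
                  sensor = "synthetic", stringsAsFactors = FALSE)
  # stable (day, source-cell) order so jitter settings never reorder rows
  d <- d[order(d$day, idx), , drop = FALSE]
  rownames(d) <- NULL
  d
}
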