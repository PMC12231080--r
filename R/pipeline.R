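# End-to-end orchestration: simulate -> interpolate -> metrics ->
# perimeter effect -> models, with a validated config, file-based stage
# outputs, and a checksummed run manifest.

#' Default run configuration
#'
#' The demo study conditions: six fires on 150 x 150 grids of 30-m pixels.
#' Each fire gets its own landscape whose aspen weight is evenly spaced
#' across \code{landscape$aspen_range} (so the patch table spans the aspen
#' cover bins), with the remaining mass split over conifer, herbaceous and
#' shrub cover in fixed ratio. Spread uses the default cover-type
#' multipliers (aspen 0.3), five contact-process sub-steps per day (so a
#' day's burn is a band several cells deep, as daily fire mapping
#' assumes) and pulsed weather coupling; detections are thinned to 5 per
#' 100 burned cells per day with 15-m positional jitter and at least one
#' detection per burning day, emulating daily satellite revisits at the
#' simulation's scale.
#'
#' @param seed integer master seed; all stage streams derive from it
#' @param nFires number of fires (default 6)
#' @return A config list accepted by [runAll()].
#' @export
defaultRunConfig <- function(seed = 1, nFires = 6) {
  list(
    seed = as.integer(seed),
    n_fires = as.integer(nFires),
    landscape = list(
      n_rows = 150, n_cols = 150, pixel_size = 30,
      aspen_range = c(0.05, 0.45),
      other_weights = c(warm_conifer = 0.5, cool_conifer = 0.25,
                        herbaceous = 0.15, shrub = 0.1),
      patchiness = 60),
    spread = list(
      base_spread_prob = 0.3, weather_coupling = 0.4, sub_steps = 5,
      max_days = 15, multipliers = list()),
    detection = list(rate = 5, jitter_sigma = 15, min_per_day = 1),
    analysis = list(half_width = 60, sample_fraction = 0.001,
                    min_detections = 10, min_aspen_fraction = 0.001,
                    min_fire_cells = 400, max_ignition_attempts = 8))
}

#' Validate a run configuration
#'
#' Checks every block before any stage runs; unknown keys are rejected.
#'
#' @param config a config list (see [defaultRunConfig()])
#' @return The config, invisibly, or an error.
#' @export
validateRunConfig <- function(config) {
  known <- c("seed", "n_fires", "landscape", "spread", "detection",
             "analysis")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  miss <- setdiff(known, names(config))
  if (length(miss))
    stop("missing config block(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(config$n_fires) || config$n_fires < 1)
    stop("n_fires must be >= 1")
  blocks <- list(
    landscape = c("n_rows", "n_cols", "pixel_size", "aspen_range",
                  "other_weights", "patchiness"),
    spread = c("base_spread_prob", "weather_coupling", "sub_steps",
               "max_days", "multipliers"),
    detection = c("rate", "jitter_sigma", "min_per_day"),
    analysis = c("half_width", "sample_fraction", "min_detections",
                 "min_aspen_fraction", "min_fire_cells",
                 "max_ignition_attempts"))
  for (b in names(blocks)) {
    unknown <- setdiff(names(config[[b]]), blocks[[b]])
    if (length(unknown))
      stop("unknown key(s) in block '", b, "': ",
           paste(unknown, collapse = ", "))
  }
  ar <- config$landscape$aspen_range
  if (length(ar) != 2 || any(ar < 0) || any(ar > 1) || ar[1] > ar[2])
    stop("aspen_range must be c(lo, hi) within [0, 1]")
  if (config$spread$base_spread_prob <= 0 || config$spread$base_spread_prob >= 1)
    stop("base_spread_prob must lie in (0, 1)")
  if (config$detection$rate <= 0) stop("detection rate must be > 0")
  invisible(config)
}

# per-fire class weights: aspen evenly spaced across the range, remaining
# mass split over the other weights proportionally
fireClassWeights <- function(config, i) {
  ar <- config$landscape$aspen_range
  n <- config$n_fires
  a <- if (n == 1) mean(ar) else ar[1] + (ar[2] - ar[1]) * (i - 1) / (n - 1)
  others <- unlist(config$landscape$other_weights)
  others <- others / sum(others) * (1 - a)
  c(aspen = a, others)
}

#' Run the full synthetic pipeline
#'
#' Executes simulate, detect, interpolate, patch metrics, perimeter effect
#' and models for \code{n_fires} fires, writing every intermediate
#' artifact under \code{outDir} (landcover and DOB ASCII grids, perimeter
#' GeoJSON, detection CSVs, the patch and FPE tables, a plain-text model
#' report) plus a JSON manifest of inputs, outputs and checksums.
#' Re-running with the same config reproduces identical checksums.
#'
#' @param config validated config list (see [defaultRunConfig()])
#' @param outDir output directory (created if needed)
#' @return The manifest, invisibly.
#' @export
runAll <- function(config = defaultRunConfig(), outDir) {
  validateRunConfig(config)
  if (missing(outDir)) stop("outDir is required")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  ls <- config$landscape
  spec <- GridSpec(ls$n_rows, ls$n_cols, ls$pixel_size)
  files <- character()
  patchRows <- list(); fpeRows <- list(); fireMeta <- list()
  for (i in seq_len(config$n_fires)) {
    id <- sprintf("fire_%02d", i)
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop("stage '", what, "' failed for ", id, ": ",
             conditionMessage(e), call. = FALSE))
    }
    lc <- stage("landscape", generateLandscape(
      spec, fireClassWeights(config, i), ls$patchiness,
      seed = deriveSeed(seed, id, "landscape")))
    set.seed(deriveSeed(seed, id, "weather"))
    weather <- as.numeric(stats::filter(stats::rnorm(config$spread$max_days),
                                        0.7, "recursive"))
    # fire archives only contain fires that grew large enough to be
    # mapped; emulate that size selection by re-attempting ignition (a
    # fresh derived stream and ignition point each time) until the burn
    # reaches min_fire_cells, keeping the largest attempt otherwise
    mult <- matrix(0.0, spec@nRows, spec@nCols)
    okc <- !is.na(classMatrix(lc))
    baseMult <- SpreadParams()@perTypeMultiplier
    if (length(config$spread$multipliers))
      baseMult[names(config$spread$multipliers)] <-
        unlist(config$spread$multipliers)
    mult[okc] <- baseMult[classMatrix(lc)[okc]]
    good <- which(mult >= 0.7)
    if (!length(good)) good <- which(mult > 0)
    fire <- NULL
    for (att in seq_len(config$analysis$max_ignition_attempts)) {
      params <- do.call(SpreadParams, c(list(
        baseSpreadProb = config$spread$base_spread_prob,
        weatherCoupling = config$spread$weather_coupling,
        subStepsPerDay = config$spread$sub_steps,
        maxDays = config$spread$max_days,
        rngSeed = deriveSeed(seed, id, "attempt", att)),
        config$spread$multipliers))
      set.seed(deriveSeed(seed, id, "ignition", att))
      ig <- good[sample.int(length(good), 1)]
      igRC <- c(((ig - 1) %% spec@nRows) + 1, ((ig - 1) %/% spec@nRows) + 1)
      cand <- stage("simulate", simulateFire(lc, igRC, params, weather, id))
      if (is.null(fire) ||
          sum(!is.na(dayMatrix(cand@trueDob))) >
            sum(!is.na(dayMatrix(fire@trueDob))))
        fire <- cand
      if (sum(!is.na(dayMatrix(fire@trueDob))) >=
            config$analysis$min_fire_cells) break
    }
    det <- stage("detections", sampleDetections(
      fire@trueDob, config$detection$rate, config$detection$jitter_sigma,
      seed = deriveSeed(seed, id),
      minPerDay = config$detection$min_per_day))
    fire@detections <- det
    validObject(fire)
    files <- c(files,
      writeLandcover(lc, file.path(outDir, paste0(id, "_landcover.asc"))),
      writePerimeterGeoJSON(fire@perimeter,
        file.path(outDir, paste0(id, "_perimeter.geojson")),
        properties = list(fire_id = id)),
      writeDetections(det, id, file.path(outDir, paste0(id, "_detections.csv"))),
      writeDOB(fire@trueDob, file.path(outDir, paste0(id, "_dob_true.asc"))))
    fpeRows[[id]] <- stage("perimeter-effect",
      fpeTable(fire, lc, config$analysis$half_width))
    filt <- passesInclusionFilters(fire, lc,
      config$analysis$min_detections, config$analysis$min_aspen_fraction)
    set.seed(deriveSeed(seed, id, "doy"))
    doy <- sample(120:270, 1)
    fireMeta[[id]] <- data.frame(fire_id = id, doy = doy,
      included = filt$pass,
      reasons = paste(filt$reasons, collapse = ";"),
      stringsAsFactors = FALSE)
    if (!filt$pass) next
    dob <- stage("interpolate", interpolateDOB(fire, spec))
    files <- c(files,
      writeDOB(dob, file.path(outDir, paste0(id, "_dob.asc"))))
    patches <- stage("metrics", {
      p <- extractPatches(dob, id)
      p <- computeSpreadMetrics(p, dob, det, lc)
      fwi <- generateCovariateGrid(spec, "FWI", params@maxDays,
        spatialScale = 900, seed = deriveSeed(seed, id))
      tmax <- generateCovariateGrid(spec, "Tmax", params@maxDays,
        spatialScale = 1500, seed = deriveSeed(seed, id))
      lapply(p, function(pp) {
        grids <- list(
          FWI = covariateGrid(fwi[[min(pp@day, params@maxDays)]] +
                                weather[min(pp@day, params@maxDays)], spec),
          Tmax = covariateGrid(tmax[[min(pp@day, params@maxDays)]], spec))
        pp@covariates <- c(
          patchCovariateMeans(pp, grids, spec,
                              config$analysis$sample_fraction, seed),
          DOY = doy + pp@day - 1)
        pp
      })
    })
    patchRows[[id]] <- patchTable(patches)
  }
  fpeAll <- do.call(rbind, fpeRows)
  meta <- do.call(rbind, fireMeta)
  utils::write.csv(fpeAll, file.path(outDir, "fpe_records.csv"),
                   row.names = FALSE)
  utils::write.csv(meta, file.path(outDir, "fires.csv"), row.names = FALSE)
  files <- c(files, file.path(outDir, "fpe_records.csv"),
             file.path(outDir, "fires.csv"))
  signs <- signTestByGroup(fpeAll)
  utils::write.csv(signs, file.path(outDir, "fpe_sign_tests.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(outDir, "fpe_sign_tests.csv"))
  modelReport <- character()
  if (length(patchRows)) {
    pt <- do.call(rbind, patchRows)
    utils::write.csv(pt, file.path(outDir, "patches.csv"), row.names = FALSE)
    files <- c(files, file.path(outDir, "patches.csv"))
    pr <- prepareResponse(pt, spec@pixelSize)
    if (length(unique(pr$fire_id)) >= 2 && nrow(pr) >= 10) {
      for (resp in c("log10_area_ha", "log10_linear_m")) {
        m <- fitMixed(pr, resp, "aspen")
        modelReport <- c(modelReport,
          utils::capture.output(print(m)), "")
      }
    } else {
      modelReport <- "too few fires/patches passed the filters for models"
    }
  } else {
    modelReport <- "no fires passed the inclusion filters"
  }
  writeLines(modelReport, file.path(outDir, "model_report.txt"))
  files <- c(files, file.path(outDir, "model_report.txt"))
  manifest <- list(
    config = config,
    fires = if (!is.null(meta)) meta$fire_id else character(),
    included = if (!is.null(meta)) meta$fire_id[meta$included] else character(),
    outputs = lapply(stats::setNames(files, basename(files)), function(f)
      unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Deterministic unit-test fixtures
#'
#' Writes one of the tiny deterministic fires used by the tests and
#' examples:
#' \describe{
#'   \item{barrier_ring}{a conifer landscape with a closed aspen annulus
#'     of zero flammability around the ignition; the simulated fire is
#'     confined inside the ring.}
#'   \item{two_day_strip}{a rectangular burn whose day-of-burning splits
#'     at a known vertical bisector between a day-1 and a day-2
#'     detection.}
#'   \item{spot_fire}{a day-1 blob plus a detached day-3 patch with no
#'     shared boundary, i.e. a discontinuous (spot-fire) day.}
#' }
#'
#' @param name fixture name
#' @param outDir output directory (created if needed)
#' @return List with the in-memory objects (landcover, fire, dob, ...)
#'   and the files written.
#' @export
makeFixture <- function(name = c("barrier_ring", "two_day_strip",
                                 "spot_fire"), outDir) {
  name <- tryCatch(match.arg(name), error = function(e)
    stop("unknown fixture '", name[1], "'; available: barrier_ring, ",
         "two_day_strip, spot_fire"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (name == "barrier_ring") {
    spec <- GridSpec(60, 60)
    cls <- matrix("warm_conifer", 60, 60)
    rr <- abs(row(cls) - 30); cc <- abs(col(cls) - 30)
    cheb <- pmax(rr, cc)
    cls[cheb >= 18 & cheb <= 20] <- "aspen"
    lc <- LandcoverGrid(spec, cls)
    params <- SpreadParams(baseSpreadProb = 0.6, aspen = 0, maxDays = 50,
                           rngSeed = 7)
    fire <- simulateFire(lc, c(30, 30), params, fireId = "barrier_ring")
    det <- sampleDetections(fire@trueDob, rate = 1e4, jitterSigma = 0,
                            seed = 7)
    fire@detections <- det
    files <- c(
      writeLandcover(lc, file.path(outDir, "barrier_ring_landcover.asc")),
      writePerimeterGeoJSON(fire@perimeter,
        file.path(outDir, "barrier_ring_perimeter.geojson"),
        properties = list(fire_id = "barrier_ring")),
      writeDetections(det, "barrier_ring",
        file.path(outDir, "barrier_ring_detections.csv")),
      writeDOB(fire@trueDob, file.path(outDir, "barrier_ring_dob.asc")))
    return(list(name = name, landcover = lc, fire = fire, files = files))
  }
  if (name == "two_day_strip") {
    spec <- GridSpec(10, 20)
    day <- matrix(NA_integer_, 10, 20)
    day[, 1:10] <- 1L
    day[, 11:20] <- 2L
    dob <- DOBGrid(spec, day)
    rings <- maskToRings(!is.na(day), spec)
    det <- data.frame(
      x = c(5.5 * 30 - 15, 15.5 * 30 - 15), y = c(5 * 30 - 15, 5 * 30 - 15),
      day = c(1L, 2L), sensor = "fixture", stringsAsFactors = FALSE)
    fire <- FireEvent("two_day_strip", rings, det, trueDob = dob)
    files <- c(
      writeDOB(dob, file.path(outDir, "two_day_strip_dob.asc")),
      writePerimeterGeoJSON(rings,
        file.path(outDir, "two_day_strip_perimeter.geojson"),
        properties = list(fire_id = "two_day_strip")),
      writeDetections(det, "two_day_strip",
        file.path(outDir, "two_day_strip_detections.csv")))
    return(list(name = name, fire = fire, dob = dob, files = files))
  }
  # spot_fire
  spec <- GridSpec(20, 20)
  day <- matrix(NA_integer_, 20, 20)
  day[8:12, 2:6] <- 1L
  day[8:12, 7] <- 2L
  day[9:11, 14:16] <- 3L
  dob <- DOBGrid(spec, day)
  rings <- maskToRings(!is.na(day), spec)
  ctr <- cellCenters(spec, which(day == 3L))
  det <- data.frame(x = c(4 * 30 - 15, mean(ctr[, 1])),
                    y = c(spec@originY - 10 * 30 + 15, mean(ctr[, 2])),
                    day = c(1L, 3L), sensor = "fixture",
                    stringsAsFactors = FALSE)
  fire <- FireEvent("spot_fire", rings, det, trueDob = dob)
  files <- c(
    writeDOB(dob, file.path(outDir, "spot_fire_dob.asc")),
    writePerimeterGeoJSON(rings,
      file.path(outDir, "spot_fire_perimeter.geojson"),
      properties = list(fire_id = "spot_fire")),
    writeDetections(det, "spot_fire",
      file.path(outDir, "spot_fire_detections.csv")))
  list(name = name, fire = fire, dob = dob, files = files)
}
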