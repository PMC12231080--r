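# Plain-text raster and vector I/O. Rasters use the ESRI ASCII grid
# format (single band, readable by GDAL/QGIS and diffable in version
# control); perimeters are GeoJSON; detections and legends are CSV.

#' Write a raster matrix as an ESRI ASCII grid
#'
#' @param values numeric or integer matrix (NA written as the nodata code)
#' @param spec the [GridSpec-class]
#' @param path output file (.asc)
#' @param nodata nodata code (default -9999)
#' @return Invisibly, the path.
#' @export
writeAsciiGrid <- function(values, spec, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", spec@nCols),
    sprintf("nrows %d", spec@nRows),
    sprintf("xllcorner %.10g", spec@originX),
    sprintf("yllcorner %.10g", spec@originY - spec@nRows * spec@pixelSize),
    sprintf("cellsize %.10g", spec@pixelSize),
    sprintf("NODATA_value %.10g", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path .asc file
#' @return List with \code{values} (matrix, nodata as NA) and \code{spec}
#'   (a [GridSpec-class]).
#' @export
readAsciiGrid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == h[["nodata_value"]]] <- NA
  spec <- GridSpec(h[["nrows"]], h[["ncols"]], h[["cellsize"]],
                   originX = h[["xllcorner"]],
                   originY = h[["yllcorner"]] + h[["nrows"]] * h[["cellsize"]])
  list(values = v, spec = spec)
}

#' Write a landcover grid (codes) to ASCII grid
#' @param landcover a [LandcoverGrid-class]
#' @param path output path
#' @return Invisibly, the path.
#' @export
writeLandcover <- function(landcover, path) {
  writeAsciiGrid(landcover@classes, landcover@spec, path)
}

#' Read a landcover grid written by [writeLandcover()]
#' @param path .asc file of class codes
#' @return A [LandcoverGrid-class].
#' @export
readLandcover <- function(path) {
  g <- readAsciiGrid(path)
  LandcoverGrid(g$spec, g$values)
}

#' Write a DOB grid to ASCII grid (nodata -1)
#' @param dob a [DOBGrid-class]
#' @param path output path
#' @return Invisibly, the path.
#' @export
writeDOB <- function(dob, path) {
  writeAsciiGrid(dob@day, dob@spec, path, nodata = -1)
}

#' Read a DOB grid written by [writeDOB()]
#' @param path .asc file of day indices
#' @return A [DOBGrid-class].
#' @export
readDOB <- function(path) {
  g <- readAsciiGrid(path)
  DOBGrid(g$spec, g$values)
}

#' Write perimeter rings as a GeoJSON MultiPolygon feature
#'
#' All rings are written as outer rings of a single MultiPolygon and are
#' meant to be interpreted under the even-odd rule (holes are just
#' additional rings). Properties are attached to the single feature.
#'
#' @param rings list of closed rings
#' @param path output .geojson file
#' @param properties named list of feature properties (e.g. fire_id, year)
#' @return Invisibly, the path.
#' @export
writePerimeterGeoJSON <- function(rings, path, properties = list()) {
  coords <- lapply(rings, function(r) {
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  })
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = properties,
      geometry = list(type = "MultiPolygon",
                      coordinates = lapply(coords, list)))))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read perimeter rings from a GeoJSON file
#'
#' Accepts Polygon and MultiPolygon geometries; every ring (outer or hole)
#' becomes one ring in the returned list, consistent with the package's
#' even-odd interpretation.
#'
#' @param path .geojson file
#' @return List with \code{rings} and \code{properties} of the first
#'   feature.
#' @export
readPerimeterGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path)
  feat <- gj$features[[1]]
  geom <- feat$geometry
  ringify <- function(rr) {
    m <- do.call(rbind, lapply(rr, function(p) as.numeric(unlist(p))))
    colnames(m) <- c("x", "y")
    m
  }
  rings <- switch(geom$type,
    Polygon = lapply(geom$coordinates, ringify),
    MultiPolygon = unlist(lapply(geom$coordinates, function(poly)
      lapply(poly, ringify)), recursive = FALSE),
    stop("unsupported geometry type: ", geom$type))
  list(rings = rings, properties = feat$properties)
}

#' Write a detections table to CSV
#'
#' Columns: fire_id, x, y, day, sensor.
#'
#' @param det detections data.frame
#' @param fireId fire identifier column value
#' @param path output .csv
#' @return Invisibly, the path.
#' @export
writeDetections <- function(det, fireId, path) {
  out <- det
  out$fire_id <- rep(fireId, nrow(det))
  out <- out[, c("fire_id", setdiff(names(det), "fire_id")), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a detections CSV written by [writeDetections()]
#' @param path .csv file
#' @return data.frame with fire_id, x, y, day, sensor.
#' @export
readDetections <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
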