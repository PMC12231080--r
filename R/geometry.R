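# Planar geometry on raster masks and polygon rings.
# Rings are n x 2 matrices (closed: first vertex repeated last); a polygon
# with holes is just a list of rings interpreted under the even-odd rule.

#' Trace the boundary of a raster mask into closed rings
#'
#' Extracts the boundary of the TRUE region of a logical matrix as closed
#' polygon rings in planar coordinates. Every cell-face segment between a
#' TRUE and a FALSE/NA cell (or the grid edge) appears in exactly one ring,
#' so even-odd point-in-polygon tests against the rings reproduce the mask
#' exactly at cell centers; holes become additional rings.
#'
#' @param mask logical matrix (nRows x nCols); NA treated as FALSE
#' @param spec the [GridSpec-class] giving the mask's geometry
#' @return List of closed rings (n x 2 coordinate matrices).
#' @export
maskToRings <- function(mask, spec) {
  mask[is.na(mask)] <- FALSE
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (!length(idx)) stop("mask has no TRUE cells")
  r <- ((idx - 1L) %% nr) + 1L
  cl <- ((idx - 1L) %/% nr) + 1L
  at <- function(rr, cc) {
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    out <- logical(length(rr))
    out[ok] <- mask[cbind(rr[ok], cc[ok])]
    out
  }
  # Corner lattice: corner (a, b), a in 0..nr, b in 0..nc, has coordinates
  # (originX + b * px, originY - a * px). Directed edges keep the burned
  # side on the left when traversing in (x, y) space with y up.
  cid <- function(a, b) a * (nc + 1L) + b + 1L
  edges <- list()
  # top face exposed (row above unburned): from TR corner (r-1, c) to TL (r-1, c-1)
  e <- !at(r - 1L, cl)
  if (any(e)) edges[[length(edges) + 1L]] <-
    cbind(cid(r[e] - 1L, cl[e]), cid(r[e] - 1L, cl[e] - 1L))
  # bottom face exposed: BL (r, c-1) -> BR (r, c)
  e <- !at(r + 1L, cl)
  if (any(e)) edges[[length(edges) + 1L]] <-
    cbind(cid(r[e], cl[e] - 1L), cid(r[e], cl[e]))
  # left face exposed: TL (r-1, c-1) -> BL (r, c-1)
  e <- !at(r, cl - 1L)
  if (any(e)) edges[[length(edges) + 1L]] <-
    cbind(cid(r[e] - 1L, cl[e] - 1L), cid(r[e], cl[e] - 1L))
  # right face exposed: BR (r, c) -> TR (r-1, c)
  e <- !at(r, cl + 1L)
  if (any(e)) edges[[length(edges) + 1L]] <-
    cbind(cid(r[e], cl[e]), cid(r[e] - 1L, cl[e]))
  em <- do.call(rbind, edges)
  # chain directed edges into rings; at degree-2 corners the successor is
  # unique, at checkerboard corners (two outgoing) any consistent pick
  # leaves even-odd semantics unchanged
  o <- order(em[, 1])
  em <- em[o, , drop = FALSE]
  starts <- em[, 1]
  used <- logical(nrow(em))
  firstAt <- match(unique(starts), starts)
  names(firstAt) <- as.character(unique(starts))
  rings <- list()
  nextUnused <- function(v) {
    i <- unname(firstAt[as.character(v)])
    if (is.na(i)) return(NA_integer_)
    while (i <= nrow(em) && starts[i] == v) {
      if (!used[i]) return(i)
      i <- i + 1L
    }
    NA_integer_
  }
  for (s in seq_len(nrow(em))) {
    if (used[s]) next
    path <- integer(0)
    i <- s
    repeat {
      used[i] <- TRUE
      path <- c(path, i)
      nxt <- nextUnused(em[i, 2])
      if (is.na(nxt)) break
      i <- nxt
      if (i == s) break
    }
    verts <- c(em[path, 1], em[path[length(path)], 2])
    a <- (verts - 1L) %/% (nc + 1L)
    b <- (verts - 1L) %% (nc + 1L)
    rings[[length(rings) + 1L]] <-
      cbind(x = spec@originX + b * spec@pixelSize,
            y = spec@originY - a * spec@pixelSize)
  }
  rings
}

#' Even-odd point-in-polygon test
#'
#' Tests whether points fall inside the region bounded by a set of rings
#' under the even-odd (crossing-parity) rule; holes are handled naturally.
#' Points exactly on a boundary edge are resolved by the crossing count and
#' should be avoided (cell centers never coincide with cell-corner lattices).
#'
#' @param x,y point coordinate vectors
#' @param rings list of closed rings (n x 2 matrices)
#' @return Logical vector, TRUE for inside points.
#' @export
pointsInRings <- function(x, y, rings) {
  cross <- integer(length(x))
  for (rg in rings) {
    x1 <- rg[-nrow(rg), 1]; y1 <- rg[-nrow(rg), 2]
    x2 <- rg[-1, 1]; y2 <- rg[-1, 2]
    keep <- y1 != y2
    x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
    for (s in seq_along(x1)) {
      spans <- (y1[s] > y) != (y2[s] > y)
      if (any(spans)) {
        xi <- x1[s] + (y[spans] - y1[s]) * (x2[s] - x1[s]) / (y2[s] - y1[s])
        hit <- xi > x[spans]
        cross[spans] <- cross[spans] + as.integer(hit)
      }
    }
  }
  cross %% 2L == 1L
}

#' Minimum distance from points to a polygon boundary
#'
#' Exact Euclidean distance from each point to the nearest segment of any
#' ring (the boundary polyline), regardless of which side the point lies on.
#'
#' @param x,y point coordinate vectors
#' @param rings list of closed rings
#' @return Numeric vector of distances in the rings' coordinate units.
#' @export
distanceToBoundary <- function(x, y, rings) {
  d2 <- rep(Inf, length(x))
  for (rg in rings) {
    x1 <- rg[-nrow(rg), 1]; y1 <- rg[-nrow(rg), 2]
    x2 <- rg[-1, 1]; y2 <- rg[-1, 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    for (s in seq_along(x1)) {
      if (len2[s] == 0) {
        dd <- (x - x1[s])^2 + (y - y1[s])^2
      } else {
        t <- ((x - x1[s]) * dx[s] + (y - y1[s]) * dy[s]) / len2[s]
        t <- pmin(1, pmax(0, t))
        dd <- (x - (x1[s] + t * dx[s]))^2 + (y - (y1[s] + t * dy[s]))^2
      }
      d2 <- pmin(d2, dd)
    }
  }
  sqrt(d2)
}

# 1-D squared-distance lower-envelope transform (Felzenszwalb &
# Huttenlocher): d[q] = min_p (q - p)^2 + f[p]. Entries of f may be Inf.
dt1d <- function(f) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (!length(fin)) return(rep(Inf, n))
  v <- integer(length(fin)); z <- numeric(length(fin) + 1L)
  k <- 1L; v[1L] <- fin[1L]; z[1L] <- -Inf; z[2L] <- Inf
  if (length(fin) > 1L) {
    for (qi in 2:length(fin)) {
      q <- fin[qi]
      repeat {
        p <- v[k]
        s <- ((f[q] + q * q) - (f[p] + p * p)) / (2 * (q - p))
        if (s <= z[k]) k <- k - 1L else break
      }
      k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- Inf
    }
  }
  d <- numeric(n); k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    d[q] <- (q - p)^2 + f[p]
  }
  d
}

# nearest-seed distance along a 1-D line; s must be sorted positions
nearest1d <- function(n, s) {
  q <- seq_len(n)
  i <- findInterval(q, s)
  lo <- ifelse(i >= 1L, s[pmax(i, 1L)], Inf)
  hi <- ifelse(i < length(s), s[pmin(i + 1L, length(s))], Inf)
  pmin(abs(q - lo), abs(hi - q))
}

#' Exact Euclidean distance transform from seed cells
#'
#' Two-pass separable exact squared-distance transform (lower-envelope
#' algorithm): for every cell of an nr x nc grid, the Euclidean distance in
#' cell units from its center to the nearest seed-cell center.
#'
#' @param nr,nc grid dimensions
#' @param seedIdx linear (column-major) indices of seed cells
#' @return Numeric nr x nc matrix of distances in cell units (Inf if no
#'   seeds).
#' @export
distanceTransform <- function(nr, nc, seedIdx) {
  D <- matrix(Inf, nr, nc)
  if (length(seedIdx)) {
    sr <- ((seedIdx - 1L) %% nr) + 1L
    sc <- ((seedIdx - 1L) %/% nr) + 1L
    for (cc in unique(sc)) {
      s <- sort(sr[sc == cc])
      D[, cc] <- nearest1d(nr, s)^2
    }
    for (rr in seq_len(nr)) D[rr, ] <- dt1d(D[rr, ])
  }
  sqrt(D)
}
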