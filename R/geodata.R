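## Raster/vector operations shared by all pipeline stages: polygon
## rasterization, mask area accounting, and nearest-cell value extraction.

# Even-odd point-in-polygon over a list of rings, vectorized over points.
# A point within eps of any ring boundary counts as inside (deterministic
# tie-break for cell centers exactly on an edge).
.pointsInRings <- function(px, py, rings, eps) {
  inside <- logical(length(px))
  onBoundary <- logical(length(px))
  for (ring in rings) {
    n <- nrow(ring)
    nxt <- c(2:n, 1L)
    for (e in seq_len(n)) {
      ax <- ring[e, 1]; ay <- ring[e, 2]
      bx <- ring[nxt[e], 1]; by <- ring[nxt[e], 2]
      cross <- (ay > py) != (by > py)
      if (any(cross)) {
        xi <- ax + (py - ay) * (bx - ax) / (by - ay)
        flip <- cross & (px < xi)
        inside[flip] <- !inside[flip]
      }
      dx <- bx - ax; dy <- by - ay
      l2 <- dx * dx + dy * dy
      if (l2 > 0) {
        t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2))
        d2 <- (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
      } else {
        d2 <- (px - ax)^2 + (py - ay)^2
      }
      onBoundary <- onBoundary | d2 <= eps * eps
    }
  }
  inside | onBoundary
}

#' Rasterize polygons onto a template grid
#'
#' A cell of the output mask is 1 exactly when its center lies inside (or on
#' the boundary of) any polygon, by the even-odd rule; holes are excluded.
#' The output is aligned exactly with the template.
#'
#' @param polys a [PolygonSet-class]; an empty set yields an all-zero mask.
#' @param template a [GridRaster-class] supplying the georeferencing.
#' @return a [GridRaster-class] of kind `"mask"`.
#' @examples
#' tmpl <- gridRaster(matrix(0, 10, 10), 0, 1000, 100)
#' sq <- rbind(c(200, 200), c(500, 200), c(500, 500), c(200, 500))
#' m <- rasterizePolygons(polygonSet(list(sq)), tmpl)
#' maskAreaKm2(m)
#' @export
rasterizePolygons <- function(polys, template) {
  stopifnot(is(polys, "PolygonSet"), is(template, "GridRaster"))
  out <- matrix(0, nRows(template), nCols(template))
  xs <- .centerXs(template)
  ys <- .centerYs(template)
  eps <- 1e-9 * template@cellSize
  for (poly in polys@polygons) {
    bb <- do.call(rbind, poly)
    cr <- which(xs >= min(bb[, 1]) - eps & xs <= max(bb[, 1]) + eps)
    rr <- which(ys >= min(bb[, 2]) - eps & ys <= max(bb[, 2]) + eps)
    if (!length(cr) || !length(rr)) next
    px <- rep(xs[cr], each = length(rr))
    py <- rep(ys[rr], times = length(cr))
    hit <- .pointsInRings(px, py, poly, eps)
    out[rr, cr] <- out[rr, cr] | matrix(hit, length(rr), length(cr))
  }
  gridRaster(out + 0, template@originX, template@originY,
             template@cellSize, kind = "mask")
}

#' Area of a binary mask in km^2
#'
#' Counts cells equal to 1 and multiplies by the cell area; nodata cells
#' contribute nothing. This is the area-accounting contract used by every
#' habitat and zone total in the pipeline.
#'
#' @param mask a [GridRaster-class] of kind `"mask"`.
#' @return area in km^2.
#' @export
maskAreaKm2 <- function(mask) {
  stopifnot(is(mask, "GridRaster"))
  if (!identical(mask@kind, "mask"))
    stop("maskAreaKm2() requires a raster of kind 'mask', got '",
         mask@kind, "'", call. = FALSE)
  sum(mask@values == 1, na.rm = TRUE) * mask@cellSize^2 / 1e6
}

#' Extract raster values at point locations
#'
#' Each point takes the value of the cell whose center is nearest
#' (nearest-cell rule, no interpolation); nodata propagates as `NA`. Point
#' order is preserved.
#'
#' @param raster a [GridRaster-class].
#' @param pts a [PointSet-class]; every point must lie within the raster
#'   extent.
#' @return numeric vector, one value per point.
#' @export
extractValuesAtPoints <- function(raster, pts) {
  stopifnot(is(raster, "GridRaster"), is(pts, "PointSet"))
  if (!nPoints(pts)) return(numeric())
  xy <- pts@coords
  ext <- rasterExtent(raster)
  bad <- which(xy[, 1] < ext["xmin"] | xy[, 1] > ext["xmax"] |
               xy[, 2] < ext["ymin"] | xy[, 2] > ext["ymax"])
  if (length(bad))
    stop("point(s) outside raster extent at index: ",
         paste(bad, collapse = ", "), call. = FALSE)
  cs <- raster@cellSize
  col <- pmin(nCols(raster), floor((xy[, 1] - raster@originX) / cs) + 1L)
  row <- pmin(nRows(raster), floor((raster@originY - xy[, 2]) / cs) + 1L)
  raster@values[cbind(row, col)]
}
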