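## Populated areas: housing density by circular moving window, thresholded
## into the binary source mask that seeds the path-distance computation.

#' Housing-density surface from residence points
#'
#' Each cell holds the number of residences within `windowRadiusM` of the
#' cell center (inclusive), divided by the window area in km^2. With the
#' default window (area exactly 1 km^2) the value is literally "houses
#' within 1 km^2 of here". Residences outside the template extent but
#' within the window of an edge cell's center still count, so density is
#' not artificially depressed at the grid edge.
#'
#' @param residences a [PointSet-class] of residence locations.
#' @param template a [GridRaster-class] supplying the georeferencing.
#' @param cfg a [DensityConfig-class].
#' @return a [GridRaster-class] of kind `"density_per_km2"`.
#' @examples
#' tmpl <- gridRaster(matrix(0, 20, 20), 0, 2000, 100)
#' res <- pointSet(runif(30, 0, 2000), runif(30, 0, 2000), "residences")
#' d <- housingDensitySurface(res, tmpl, densityConfig())
#' populatedMask(d, densityConfig())
#' @export
housingDensitySurface <- function(residences, template,
                                  cfg = densityConfig()) {
  stopifnot(is(residences, "PointSet"), is(template, "GridRaster"),
            is(cfg, "DensityConfig"))
  validObject(cfg)
  R <- cfg@windowRadiusM
  counts <- matrix(0, nRows(template), nCols(template))
  xs <- .centerXs(template)
  ys <- .centerYs(template)
  xy <- residences@coords
  for (i in seq_len(nrow(xy))) {
    cr <- which(abs(xs - xy[i, 1]) <= R)
    rr <- which(abs(ys - xy[i, 2]) <= R)
    if (!length(cr) || !length(rr)) next
    within <- outer((ys[rr] - xy[i, 2])^2, (xs[cr] - xy[i, 1])^2, "+") <= R * R
    counts[rr, cr] <- counts[rr, cr] + within
  }
  areaKm2 <- pi * R * R / 1e6
  gridRaster(counts / areaKm2, template@originX, template@originY,
             template@cellSize, kind = "density_per_km2")
}

#' Populated-area mask from a density surface
#'
#' A cell is populated exactly when its housing density is strictly greater
#' than the threshold (default 6.25 houses/km^2). The inequality is strict:
#' a cell at exactly the threshold is not populated. Nodata propagates.
#'
#' @param density a [GridRaster-class] of kind `"density_per_km2"`.
#' @param cfg a [DensityConfig-class].
#' @return a [GridRaster-class] of kind `"mask"`.
#' @export
populatedMask <- function(density, cfg = densityConfig()) {
  stopifnot(is(density, "GridRaster"), is(cfg, "DensityConfig"))
  if (!identical(density@kind, "density_per_km2"))
    stop("populatedMask() requires a raster of kind 'density_per_km2'",
         call. = FALSE)
  v <- (density@values > cfg@thresholdPerKm2) + 0
  gridRaster(v, density@originX, density@originY, density@cellSize,
             kind = "mask")
}
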