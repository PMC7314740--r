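#' Construct a GridRaster
#'
#' @param values numeric matrix of cell values; `NA` is nodata. Row 1 is the
#'   northernmost row.
#' @param originX,originY coordinates (m) of the north-west corner of the
#'   grid.
#' @param cellSize cell edge length in meters.
#' @param kind one of `"elevation_m"`, `"density_per_km2"`, `"distance_m"`,
#'   `"mask"`.
#' @return a [GridRaster-class].
#' @examples
#' r <- gridRaster(matrix(0, 4, 5), 0, 400, 100, "elevation_m")
#' rasterExtent(r)
#' @export
gridRaster <- function(values, originX = 0, originY = nrow(values) * cellSize,
                       cellSize = 1, kind = "elevation_m") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("GridRaster", values = values, originX = as.numeric(originX),
      originY = as.numeric(originY), cellSize = as.numeric(cellSize),
      kind = kind)
}

#' Construct a PointSet
#'
#' @param x,y numeric coordinate vectors in projected meters, or `x` a
#'   two-column matrix.
#' @param label role tag (`"residences"`, `"occurrences"`, `"available"`, or
#'   free text).
#' @return a [PointSet-class].
#' @examples
#' pointSet(c(100, 200), c(50, 80), label = "residences")
#' @export
pointSet <- function(x = numeric(), y = NULL, label = "points") {
  coords <- if (is.matrix(x) && is.null(y)) x[, 1:2, drop = FALSE]
            else cbind(as.numeric(x), as.numeric(y))
  if (!nrow(coords)) coords <- matrix(numeric(), 0L, 2L)
  colnames(coords) <- c("x", "y")
  storage.mode(coords) <- "double"
  new("PointSet", coords = coords, label = label)
}

#' Construct a PolygonSet
#'
#' @param polygons a list of polygons. Each polygon is either a single ring
#'   (two-column vertex matrix, implicitly closed) or a list of rings where
#'   the first ring is the outer boundary and the rest are holes.
#' @param names optional character identifier per polygon; defaults to
#'   `"poly1"`, `"poly2"`, ...
#' @return a [PolygonSet-class].
#' @examples
#' sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
#' polygonSet(list(sq), names = "unit")
#' @export
polygonSet <- function(polygons = list(), names = NULL) {
  polys <- lapply(polygons, function(p) {
    if (is.matrix(p)) p <- list(p)
    lapply(p, function(ring) {
      ring <- as.matrix(ring)[, 1:2, drop = FALSE]
      storage.mode(ring) <- "double"
      # drop an explicit closing vertex; rings are implicitly closed
      n <- nrow(ring)
      if (n > 3L && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
      ring
    })
  })
  if (is.null(names))
    names <- if (length(polys)) paste0("poly", seq_along(polys))
             else character(0)
  new("PolygonSet", polygons = polys, polyNames = as.character(names))
}

#' Housing-density configuration
#'
#' @param windowRadiusM circular moving-window radius in meters. The default
#'   `sqrt(1e6 / pi)` (about 564.19 m) makes the window area exactly 1 km^2.
#' @param thresholdPerKm2 density above which (strictly) a cell is
#'   classified as a populated area; default 6.25 houses/km^2.
#' @return a [DensityConfig-class].
#' @export
densityConfig <- function(windowRadiusM = sqrt(1e6 / pi),
                          thresholdPerKm2 = 6.25) {
  new("DensityConfig", windowRadiusM = as.numeric(windowRadiusM),
      thresholdPerKm2 = as.numeric(thresholdPerKm2))
}

#' Zone-threshold configuration
#'
#' @param humanImpactM human-impact path-distance threshold in meters
#'   (default 1,920).
#' @param forayM free-roaming dog foray path-distance threshold in meters
#'   (default 10,900).
#' @return a [ZoneConfig-class].
#' @export
zoneConfig <- function(humanImpactM = 1920, forayM = 10900) {
  new("ZoneConfig", humanImpactM = as.numeric(humanImpactM),
      forayM = as.numeric(forayM))
}

#' Assemble an effective-habitat report from areas
#'
#' Computes the percent reduction and wraps the three areas in an
#' [EffectiveHabitatReport-class]. Useful both inside [effectiveHabitat()]
#' and for accounting from already-tabulated areas.
#'
#' @param baselineKm2 baseline habitat area, km^2.
#' @param effectiveIKm2 habitat beyond the human-impact distance, km^2.
#' @param effectiveIIKm2 habitat beyond the dog foray distance, km^2.
#' @param nodataKm2 habitat area with nodata path distance, km^2.
#' @return an [EffectiveHabitatReport-class].
#' @examples
#' r <- effectiveHabitatReport(385.2, 380.3, 108.7)
#' round(r@reductionIIPct)  # 72
#' @export
effectiveHabitatReport <- function(baselineKm2, effectiveIKm2, effectiveIIKm2,
                                   nodataKm2 = 0) {
  red <- if (baselineKm2 > 0)
    100 * (baselineKm2 - effectiveIIKm2) / baselineKm2 else 0
  new("EffectiveHabitatReport",
      baselineKm2 = as.numeric(baselineKm2),
      effectiveIKm2 = as.numeric(effectiveIKm2),
      effectiveIIKm2 = as.numeric(effectiveIIKm2),
      reductionIIPct = red, nodataKm2 = as.numeric(nodataKm2))
}
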