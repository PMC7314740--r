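## Terrain-aware multi-source path distance: the computational kernel of
## the analysis. Distance accumulates surface length — the hypotenuse of
## horizontal step and elevation change — so steep terrain lengthens paths.

#' Path-distance surface away from source cells
#'
#' Computes, for every raster cell, the minimum accumulated surface length
#' over all 8-connected lattice paths from any source cell. The cost of a
#' step between adjacent cells a and b is `sqrt(h^2 + (z_a - z_b)^2)` with
#' `h = cellSize` for rook moves and `cellSize * sqrt(2)` for diagonal
#' moves. Computed by Dijkstra's algorithm (compiled), which is exact for
#' non-negative step costs. Nodata elevation cells are impassable barriers:
#' paths route around them, and cells unreachable from every source carry
#' nodata.
#'
#' @param dem a [GridRaster-class] of kind `"elevation_m"`.
#' @param sources a [GridRaster-class] mask of source (populated-area)
#'   cells, aligned with `dem`.
#' @return a [PathDistanceSurface-class].
#' @examples
#' dem <- gridRaster(matrix(0, 5, 5), 0, 150, 30)
#' src <- gridRaster(matrix(c(1, rep(0, 24)), 5, 5), 0, 150, 30, "mask")
#' d <- surfacePathDistance(dem, src)
#' maxFiniteDistance(d)
#' @export
surfacePathDistance <- function(dem, sources) {
  stopifnot(is(dem, "GridRaster"), is(sources, "GridRaster"))
  if (!identical(dem@kind, "elevation_m"))
    stop("'dem' must be a raster of kind 'elevation_m'", call. = FALSE)
  if (!identical(sources@kind, "mask"))
    stop("'sources' must be a raster of kind 'mask'", call. = FALSE)
  .stopIfMisaligned(dem, sources, "'dem' and 'sources'")
  if (!any(sources@values == 1, na.rm = TRUE))
    stop("no source cells: the source mask contains no 1 cells",
         call. = FALSE)
  src <- sources@values
  src[is.na(src)] <- 0
  storage.mode(src) <- "integer"
  d <- .dijkstraGrid(dem@values, src, dem@cellSize)
  new("PathDistanceSurface",
      distance = gridRaster(d, dem@originX, dem@originY, dem@cellSize,
                            kind = "distance_m"),
      sources = sources, dem = dem)
}

#' Maximum finite path distance on a surface
#'
#' @param surface a [PathDistanceSurface-class].
#' @return the maximum over cells with finite distance, in meters; nodata
#'   cells are ignored. Errors if no cell has a finite distance.
#' @export
maxFiniteDistance <- function(surface) {
  stopifnot(is(surface, "PathDistanceSurface"))
  d <- surface@distance@values
  fin <- d[!is.na(d)]
  if (!length(fin))
    stop("surface has no finite distances", call. = FALSE)
  max(fin)
}
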