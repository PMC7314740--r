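#' @name dogedge-accessors
#' @title Accessors for the core data classes
#'
#' @description Small accessor generics used instead of direct slot access:
#' raster geometry (`nRows`, `nCols`, `cellSize`, `origin`, `rasterExtent`),
#' raster payload (`gridValues`, `rasterKind`), point sets (`nPoints`,
#' `pointCoords`, `pointLabel`), polygon sets (`nPolygons`, `polygonNames`,
#' `polygonRings`) and path-distance surfaces (`distanceRaster`,
#' `sourceMask`, `demRaster`).
#'
#' @param x an object of the documented class.
#' @param i polygon index.
#' @return the slot contents; geometry accessors return numerics,
#'   `rasterExtent` a named vector `c(xmin, xmax, ymin, ymax)` of the outer
#'   raster edges.
NULL

#' @rdname dogedge-accessors
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))
#' @rdname dogedge-accessors
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))
#' @rdname dogedge-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname dogedge-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname dogedge-accessors
#' @export
setGeneric("rasterExtent", function(x) standardGeneric("rasterExtent"))
#' @rdname dogedge-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname dogedge-accessors
#' @export
setGeneric("rasterKind", function(x) standardGeneric("rasterKind"))
#' @rdname dogedge-accessors
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))
#' @rdname dogedge-accessors
#' @export
setGeneric("pointCoords", function(x) standardGeneric("pointCoords"))
#' @rdname dogedge-accessors
#' @export
setGeneric("pointLabel", function(x) standardGeneric("pointLabel"))
#' @rdname dogedge-accessors
#' @export
setGeneric("nPolygons", function(x) standardGeneric("nPolygons"))
#' @rdname dogedge-accessors
#' @export
setGeneric("polygonNames", function(x) standardGeneric("polygonNames"))
#' @rdname dogedge-accessors
#' @export
setGeneric("polygonRings", function(x, i) standardGeneric("polygonRings"))
#' @rdname dogedge-accessors
#' @export
setGeneric("distanceRaster", function(x) standardGeneric("distanceRaster"))
#' @rdname dogedge-accessors
#' @export
setGeneric("sourceMask", function(x) standardGeneric("sourceMask"))
#' @rdname dogedge-accessors
#' @export
setGeneric("demRaster", function(x) standardGeneric("demRaster"))
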