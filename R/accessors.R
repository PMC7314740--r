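#' @rdname dogedge-accessors
setMethod("nRows", "GridRaster", function(x) nrow(x@values))
#' @rdname dogedge-accessors
setMethod("nCols", "GridRaster", function(x) ncol(x@values))
#' @rdname dogedge-accessors
setMethod("cellSize", "GridRaster", function(x) x@cellSize)
#' @rdname dogedge-accessors
setMethod("origin", "GridRaster", function(x) c(x = x@originX, y = x@originY))
#' @rdname dogedge-accessors
setMethod("rasterExtent", "GridRaster", function(x) {
  c(xmin = x@originX,
    xmax = x@originX + ncol(x@values) * x@cellSize,
    ymin = x@originY - nrow(x@values) * x@cellSize,
    ymax = x@originY)
})
#' @rdname dogedge-accessors
setMethod("gridValues", "GridRaster", function(x) x@values)
#' @rdname dogedge-accessors
setMethod("rasterKind", "GridRaster", function(x) x@kind)

#' @rdname dogedge-accessors
setMethod("nPoints", "PointSet", function(x) nrow(x@coords))
#' @rdname dogedge-accessors
setMethod("pointCoords", "PointSet", function(x) x@coords)
#' @rdname dogedge-accessors
setMethod("pointLabel", "PointSet", function(x) x@label)

#' @rdname dogedge-accessors
setMethod("nPolygons", "PolygonSet", function(x) length(x@polygons))
#' @rdname dogedge-accessors
setMethod("polygonNames", "PolygonSet", function(x) x@polyNames)
#' @rdname dogedge-accessors
setMethod("polygonRings", "PolygonSet", function(x, i) x@polygons[[i]])

#' @rdname dogedge-accessors
setMethod("distanceRaster", "PathDistanceSurface", function(x) x@distance)
#' @rdname dogedge-accessors
setMethod("sourceMask", "PathDistanceSurface", function(x) x@sources)
#' @rdname dogedge-accessors
setMethod("demRaster", "PathDistanceSurface", function(x) x@dem)

setMethod("show", "GridRaster", function(object) {
  v <- object@values
  fin <- v[!is.na(v)]
  cat("GridRaster of kind '", object@kind, "'\n", sep = "")
  cat(sprintf("  %d rows x %d cols, cell size %g m\n",
              nrow(v), ncol(v), object@cellSize))
  cat(sprintf("  NW origin (%g, %g); extent %g x %g km\n",
              object@originX, object@originY,
              ncol(v) * object@cellSize / 1000,
              nrow(v) * object@cellSize / 1000))
  if (length(fin))
    cat(sprintf("  values: min %.4g, max %.4g; %d nodata cell(s)\n",
                min(fin), max(fin), sum(is.na(v))))
  else cat("  all cells nodata\n")
  invisible(NULL)
})

setMethod("show", "PointSet", function(object) {
  cat(sprintf("PointSet '%s' with %d point(s)\n",
              object@label, nrow(object@coords)))
  if (nrow(object@coords)) {
    cat(sprintf("  x range [%g, %g], y range [%g, %g] m\n",
                min(object@coords[, 1]), max(object@coords[, 1]),
                min(object@coords[, 2]), max(object@coords[, 2])))
  }
  invisible(NULL)
})

setMethod("show", "PolygonSet", function(object) {
  cat(sprintf("PolygonSet with %d polygon(s)\n", length(object@polygons)))
  if (length(object@polygons))
    cat("  names:", paste(object@polyNames, collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "PathDistanceSurface", function(object) {
  d <- object@distance@values
  fin <- d[!is.na(d)]
  cat("PathDistanceSurface\n")
  cat(sprintf("  %d x %d cells, cell size %g m\n",
              nrow(d), ncol(d), object@distance@cellSize))
  cat(sprintf("  %d source cell(s); ", sum(object@sources@values == 1,
                                           na.rm = TRUE)))
  if (length(fin))
    cat(sprintf("finite distances 0 to %.1f m (%d nodata)\n",
                max(fin), sum(is.na(d))))
  else cat("no finite distances\n")
  invisible(NULL)
})

setMethod("show", "EffectiveHabitatReport", function(object) {
  cat("EffectiveHabitatReport (areas km^2, printed to one decimal)\n")
  cat(sprintf("  baseline habitat:          %.1f\n", object@baselineKm2))
  cat(sprintf("  effective I (human only):  %.1f\n", object@effectiveIKm2))
  cat(sprintf("  effective II (human+dog):  %.1f\n", object@effectiveIIKm2))
  cat(sprintf("  reduction (II vs baseline): %.0f%%\n", object@reductionIIPct))
  if (object@nodataKm2 > 0)
    cat(sprintf("  note: %.1f km^2 of habitat unreachable (counted dog-free)\n",
                object@nodataKm2))
  invisible(NULL)
})

setMethod("show", "UseAvailabilityResult", function(object) {
  cat("UseAvailabilityResult\n")
  cat(sprintf("  used: n = %d, mean %.1f km; available: n = %d, mean %.1f km (sd %.1f)\n",
              object@nUsed, object@meanUsedKm,
              object@nAvailable, object@meanAvailKm, object@sdAvailKm))
  cat(sprintf("  shift: %.1f km (%s availability SDs)\n", object@shiftKm,
              if (is.na(object@shiftSd)) "undefined"
              else sprintf("%.2f", object@shiftSd)))
  cat(sprintf("  used beyond foray distance: %.0f%%\n",
              100 * object@fracUsedBeyondForay))
  invisible(NULL)
})

setMethod("show", "AvoidanceModel", function(object) {
  cat(sprintf("AvoidanceModel: midpoint theta = %.0f m, softness s = %.0f m",
              object@thetaM, object@sM))
  if (!is.na(object@logLik)) cat(sprintf(" (logLik %.2f)", object@logLik))
  cat("\n")
  invisible(NULL)
})

setMethod("show", "JenksResult", function(object) {
  cat(sprintf("JenksResult: k = %d, GVF = %.4f\n", object@k, object@gvf))
  if (length(object@breaks))
    cat("  breaks:", paste(signif(object@breaks, 6), collapse = ", "), "\n")
  invisible(NULL)
})
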