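## Core S4 classes for the planar raster/vector data model and the
## configuration and result containers used throughout the pipeline.
## All coordinates are in a projected system with units of meters; row 1 of
## a raster is the northernmost row and cell (r, c) has its center at
## (originX + (c - 0.5) * cellSize, originY - (r - 0.5) * cellSize).

.RASTER_KINDS <- c("elevation_m", "density_per_km2", "distance_m", "mask")

#' GridRaster: a georeferenced planar raster
#'
#' A single-band raster on a square-cell grid in a projected coordinate
#' system (meters). `NA` is the nodata marker. The `kind` slot records the
#' semantics of the values: elevation in meters, housing density in houses
#' per square kilometer, accumulated path distance in meters, or a binary
#' mask (values restricted to 0, 1 and `NA`).
#'
#' @slot values numeric matrix, `nRows x nCols`; `NA` is nodata.
#' @slot originX,originY coordinates (m) of the outer corner of cell (1, 1),
#'   i.e. the north-west corner of the grid.
#' @slot cellSize edge length of a cell in meters (square cells).
#' @slot kind one of `"elevation_m"`, `"density_per_km2"`, `"distance_m"`,
#'   `"mask"`.
#'
#' @seealso [gridRaster()] for the user-facing constructor.
#' @exportClass GridRaster
setClass("GridRaster",
  representation(
    values = "matrix",
    originX = "numeric",
    originY = "numeric",
    cellSize = "numeric",
    kind = "character"
  )
)

setValidity("GridRaster", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (nrow(v) < 1L || ncol(v) < 1L)
    msg <- c(msg, "raster must have at least one row and one column")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "'cellSize' must be a single positive finite number")
  if (length(object@originX) != 1L || !is.finite(object@originX) ||
      length(object@originY) != 1L || !is.finite(object@originY))
    msg <- c(msg, "origin coordinates must be single finite numbers")
  if (length(object@kind) != 1L || !(object@kind %in% .RASTER_KINDS))
    msg <- c(msg, sprintf("'kind' must be one of: %s",
                          paste(.RASTER_KINDS, collapse = ", ")))
  if (is.numeric(v)) {
    if (any(is.infinite(v)))
      msg <- c(msg, "values must be finite or NA (nodata)")
    fin <- v[!is.na(v)]
    if (identical(object@kind, "mask") && length(fin) &&
        !all(fin %in% c(0, 1)))
      msg <- c(msg, "mask rasters may contain only 0, 1 and NA")
    if (identical(object@kind, "distance_m") && length(fin) && any(fin < 0))
      msg <- c(msg, "distance rasters may not contain negative values")
  }
  if (length(msg)) msg else TRUE
})

#' PointSet: locations in projected meters
#'
#' @slot coords two-column numeric matrix (x, y) in meters; may have zero
#'   rows.
#' @slot label free-text role tag, conventionally one of `"residences"`,
#'   `"occurrences"`, `"available"`.
#'
#' @seealso [pointSet()]
#' @exportClass PointSet
setClass("PointSet",
  representation(coords = "matrix", label = "character")
)

setValidity("PointSet", function(object) {
  msg <- character()
  if (!is.numeric(object@coords) || ncol(object@coords) != 2L)
    msg <- c(msg, "'coords' must be a two-column numeric matrix")
  else if (nrow(object@coords) && !all(is.finite(object@coords)))
    msg <- c(msg, "point coordinates must be finite")
  if (length(object@label) != 1L)
    msg <- c(msg, "'label' must be a single string")
  if (length(msg)) msg else TRUE
})

#' PolygonSet: simple polygons in projected meters
#'
#' Each polygon is a list of rings; the first ring is the outer boundary and
#' any further rings are holes (even-odd interpretation). Rings are
#' two-column (x, y) matrices of at least three distinct vertices and are
#' treated as implicitly closed.
#'
#' @slot polygons list of polygons, each a list of ring matrices.
#' @slot polyNames character identifier per polygon.
#'
#' @seealso [polygonSet()]
#' @exportClass PolygonSet
setClass("PolygonSet",
  representation(polygons = "list", polyNames = "character")
)

setValidity("PolygonSet", function(object) {
  msg <- character()
  if (length(object@polyNames) != length(object@polygons))
    msg <- c(msg, "'polyNames' must have one entry per polygon")
  for (i in seq_along(object@polygons)) {
    poly <- object@polygons[[i]]
    if (!is.list(poly) || !length(poly)) {
      msg <- c(msg, sprintf("polygon %d must be a non-empty list of rings", i))
      next
    }
    for (ring in poly) {
      if (!is.matrix(ring) || ncol(ring) != 2L || nrow(ring) < 3L) {
        msg <- c(msg, sprintf(
          "polygon %d: each ring must be a matrix with >= 3 vertices", i))
      } else if (!all(is.finite(ring))) {
        msg <- c(msg, sprintf("polygon %d: ring vertices must be finite", i))
      } else if (abs(.ringArea(ring)) <= 0) {
        msg <- c(msg, sprintf("polygon %d: ring has zero area", i))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' PathDistanceSurface: terrain-aware distance from source cells
#'
#' Holds the accumulated path-distance raster together with the source mask
#' it was seeded from and the elevation model it was computed over. Every
#' source cell has distance exactly 0; cells on nodata elevation, and cells
#' unreachable from any source, carry `NA`.
#'
#' @slot distance [GridRaster-class] of kind `"distance_m"`.
#' @slot sources [GridRaster-class] mask of the seed (populated-area) cells.
#' @slot dem [GridRaster-class] of kind `"elevation_m"` used for the
#'   vertical component.
#'
#' @seealso [surfacePathDistance()]
#' @exportClass PathDistanceSurface
setClass("PathDistanceSurface",
  representation(
    distance = "GridRaster",
    sources = "GridRaster",
    dem = "GridRaster"
  )
)

setValidity("PathDistanceSurface", function(object) {
  msg <- character()
  if (!identical(object@distance@kind, "distance_m"))
    msg <- c(msg, "'distance' raster must have kind 'distance_m'")
  if (!identical(object@sources@kind, "mask"))
    msg <- c(msg, "'sources' raster must have kind 'mask'")
  if (!identical(object@dem@kind, "elevation_m"))
    msg <- c(msg, "'dem' raster must have kind 'elevation_m'")
  if (!.sameGeoref(object@distance, object@sources) ||
      !.sameGeoref(object@distance, object@dem))
    msg <- c(msg, "distance, sources and dem must share georeferencing")
  else {
    src <- !is.na(object@sources@values) & object@sources@values == 1 &
      !is.na(object@dem@values)
    d <- object@distance@values[src]
    if (length(d) && (any(is.na(d)) || any(d != 0)))
      msg <- c(msg, "source cells must have distance exactly 0")
  }
  if (length(msg)) msg else TRUE
})

#' DensityConfig: housing-density window and populated-area threshold
#'
#' Defaults give a circular moving window of area exactly 1 km^2 (radius
#' `sqrt(1e6 / pi)` = 564.19 m), so the default threshold of 6.25
#' houses/km^2 reads directly as "more than 6 houses within 1 km^2".
#'
#' @slot windowRadiusM moving-window radius in meters (> 0).
#' @slot thresholdPerKm2 housing density (houses/km^2) above which — strictly
#'   — a cell is classified as populated.
#'
#' @seealso [densityConfig()]
#' @exportClass DensityConfig
setClass("DensityConfig",
  representation(windowRadiusM = "numeric", thresholdPerKm2 = "numeric"),
  prototype(windowRadiusM = sqrt(1e6 / pi), thresholdPerKm2 = 6.25)
)

setValidity("DensityConfig", function(object) {
  msg <- character()
  if (length(object@windowRadiusM) != 1L ||
      !is.finite(object@windowRadiusM) || object@windowRadiusM <= 0)
    msg <- c(msg, "'windowRadiusM' must be a single positive number")
  if (length(object@thresholdPerKm2) != 1L ||
      !is.finite(object@thresholdPerKm2) || object@thresholdPerKm2 < 0)
    msg <- c(msg, "'thresholdPerKm2' must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' ZoneConfig: human-impact and dog-foray distance thresholds
#'
#' Defaults are the field estimates used throughout the analysis: 1,920 m
#' for the edge effect of human residences alone and 10,900 m for the
#' maximum observed foray path-distance of free-roaming dogs.
#'
#' @slot humanImpactM human-impact path-distance threshold (m).
#' @slot forayM dog foray path-distance threshold (m); must be >=
#'   `humanImpactM`.
#'
#' @seealso [zoneConfig()]
#' @exportClass ZoneConfig
setClass("ZoneConfig",
  representation(humanImpactM = "numeric", forayM = "numeric"),
  prototype(humanImpactM = 1920, forayM = 10900)
)

setValidity("ZoneConfig", function(object) {
  msg <- character()
  if (length(object@humanImpactM) != 1L || !is.finite(object@humanImpactM) ||
      object@humanImpactM < 0)
    msg <- c(msg, "'humanImpactM' must be a single non-negative number")
  if (length(object@forayM) != 1L || !is.finite(object@forayM) ||
      object@forayM < object@humanImpactM)
    msg <- c(msg, "'forayM' must be >= 'humanImpactM'")
  if (length(msg)) msg else TRUE
})

#' EffectiveHabitatReport: baseline vs effective habitat accounting
#'
#' Areas in km^2: baseline habitat, effective habitat I (beyond the
#' human-impact distance) and effective habitat II (beyond the dog foray
#' distance), with the percent reduction from baseline to effective II.
#' `nodataKm2` records habitat area whose path distance is nodata
#' (unreachable enclaves); such cells are counted as beyond every threshold.
#'
#' @slot baselineKm2,effectiveIKm2,effectiveIIKm2 areas in km^2.
#' @slot reductionIIPct percent reduction, `100 * (baseline - effectiveII) /
#'   baseline` (0 when baseline is 0).
#' @slot nodataKm2 habitat area with nodata distance, km^2.
#'
#' @seealso [effectiveHabitat()], [effectiveHabitatReport()]
#' @exportClass EffectiveHabitatReport
setClass("EffectiveHabitatReport",
  representation(
    baselineKm2 = "numeric",
    effectiveIKm2 = "numeric",
    effectiveIIKm2 = "numeric",
    reductionIIPct = "numeric",
    nodataKm2 = "numeric"
  ),
  prototype(nodataKm2 = 0)
)

setValidity("EffectiveHabitatReport", function(object) {
  msg <- character()
  b <- object@baselineKm2; e1 <- object@effectiveIKm2
  e2 <- object@effectiveIIKm2
  if (any(!is.finite(c(b, e1, e2))) || b < 0)
    msg <- c(msg, "areas must be finite and baseline non-negative")
  else {
    tol <- 1e-9 * max(1, b)
    if (!(e2 <= e1 + tol && e1 <= b + tol && e2 >= -tol))
      msg <- c(msg, "areas must satisfy 0 <= effectiveII <= effectiveI <= baseline")
  }
  if (length(msg)) msg else TRUE
})

#' UseAvailabilityResult: shift of use away from populated areas
#'
#' Summary of occurrence ("used") path distances against available-habitat
#' path distances. Distances are reported in kilometers. `shiftSd` is the
#' shift expressed in availability standard deviations (`NA` when the
#' availability distances have zero variance).
#'
#' @slot nUsed,nAvailable sample sizes.
#' @slot meanUsedKm,meanAvailKm,sdAvailKm summary statistics (km); the
#'   standard deviation uses the n - 1 denominator.
#' @slot shiftKm `meanUsedKm - meanAvailKm`.
#' @slot shiftSd `shiftKm / sdAvailKm`.
#' @slot fracUsedBeyondForay proportion of used distances strictly greater
#'   than the foray threshold.
#'
#' @seealso [summarizeShift()]
#' @exportClass UseAvailabilityResult
setClass("UseAvailabilityResult",
  representation(
    nUsed = "integer",
    nAvailable = "integer",
    meanUsedKm = "numeric",
    meanAvailKm = "numeric",
    sdAvailKm = "numeric",
    shiftKm = "numeric",
    shiftSd = "numeric",
    fracUsedBeyondForay = "numeric"
  )
)

setValidity("UseAvailabilityResult", function(object) {
  msg <- character()
  f <- object@fracUsedBeyondForay
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1)
    msg <- c(msg, "'fracUsedBeyondForay' must be in [0, 1]")
  if (object@nUsed < 1L || object@nAvailable < 1L)
    msg <- c(msg, "both samples must be non-empty")
  if (length(msg)) msg else TRUE
})

#' AvoidanceModel: logistic distance-avoidance response
#'
#' Parameterizes habitat-use weight as a logistic function of path distance,
#' `w(d) = 1 / (1 + exp(-(d - theta) / s))`: `theta` is the avoidance
#' midpoint (m) and `s` the softness scale (m). Fitted by [fitAvoidance()].
#'
#' @slot thetaM avoidance midpoint in meters.
#' @slot sM softness scale in meters (> 0).
#' @slot logLik maximized log-likelihood (NA for hand-constructed models).
#'
#' @exportClass AvoidanceModel
setClass("AvoidanceModel",
  representation(thetaM = "numeric", sM = "numeric", logLik = "numeric"),
  prototype(logLik = NA_real_)
)

setValidity("AvoidanceModel", function(object) {
  if (length(object@sM) != 1L || !is.finite(object@sM) || object@sM <= 0)
    "'sM' must be a single positive number" else TRUE
})

#' JenksResult: optimal natural-breaks classification
#'
#' Globally optimal partition of one-dimensional values into `k` contiguous
#' classes minimizing the within-class sum of squared deviations (Fisher's
#' exact dynamic program). `gvf` is the goodness-of-variance fit,
#' `1 - SSD_within / SSD_total`.
#'
#' @slot breaks ascending numeric vector of k - 1 class boundaries, each the
#'   midpoint between the adjacent class-edge values.
#' @slot gvf goodness-of-variance fit in `[0, 1]`.
#' @slot assignment integer class index (1..k) per input value, in input
#'   order.
#' @slot k number of classes.
#' @slot withinSSD total within-class sum of squared deviations.
#'
#' @seealso [jenksBreaks()]
#' @exportClass JenksResult
setClass("JenksResult",
  representation(
    breaks = "numeric",
    gvf = "numeric",
    assignment = "integer",
    k = "integer",
    withinSSD = "numeric"
  )
)

setValidity("JenksResult", function(object) {
  msg <- character()
  if (length(object@breaks) &&
      any(diff(object@breaks) <= 0))
    msg <- c(msg, "'breaks' must be strictly ascending")
  if (!is.na(object@gvf) && (object@gvf < -1e-12 || object@gvf > 1 + 1e-12))
    msg <- c(msg, "'gvf' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
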