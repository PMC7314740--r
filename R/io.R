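## File I/O. Rasters travel as Esri ASCII Grid (plain text, lossless for
## georeferencing, values at full double precision); vectors as GeoJSON or,
## for bare point sets, CSV with columns x,y. All stages of the pipeline
## read and write only these formats.

#' Write a raster as an Esri ASCII Grid
#'
#' Values are written at full double precision (17 significant digits) so a
#' read/write round trip is lossless; nodata cells are written as the
#' `NODATA_value` (-9999 by default, chosen automatically if -9999 occurs as
#' a real value).
#'
#' @param x a [GridRaster-class].
#' @param path output file path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(x, path) {
  stopifnot(is(x, "GridRaster"))
  v <- x@values
  nodata <- -9999
  while (any(v == nodata, na.rm = TRUE)) nodata <- nodata * 10 - 1
  hdr <- c(
    paste("ncols", ncol(v)),
    paste("nrows", nrow(v)),
    paste("xllcorner", formatC(x@originX, digits = 17, format = "g")),
    paste("yllcorner",
          formatC(x@originY - nrow(v) * x@cellSize, digits = 17, format = "g")),
    paste("cellsize", formatC(x@cellSize, digits = 17, format = "g")),
    paste("NODATA_value", formatC(nodata, digits = 17, format = "g"))
  )
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(row)
    paste(formatC(row, digits = 17, format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an Esri ASCII Grid raster
#'
#' @param path file path.
#' @param kind raster kind to tag the result with (the format itself does
#'   not record semantics); one of `"elevation_m"`, `"density_per_km2"`,
#'   `"distance_m"`, `"mask"`.
#' @return a [GridRaster-class].
#' @export
readAsciiGrid <- function(path, kind = "elevation_m") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not a valid ASCII grid: missing header field(s)", call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop("ASCII grid body has ", length(vals), " values, expected ",
         nr * nc, call. = FALSE)
  v <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) v[v == hdr$nodata_value] <- NA
  cs <- hdr$cellsize
  ox <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  oyll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  gridRaster(v, ox, oyll + nr * cs, cs, kind = kind)
}

#' Write a point set as CSV
#'
#' @param pts a [PointSet-class].
#' @param path output file path; columns `x,y` in projected meters.
#' @return `path`, invisibly.
#' @export
writePointsCsv <- function(pts, path) {
  stopifnot(is(pts, "PointSet"))
  df <- as.data.frame(pts@coords)
  names(df) <- c("x", "y")
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a point set from CSV
#'
#' @param path CSV file with numeric columns `x` and `y`.
#' @param label role tag for the resulting [PointSet-class].
#' @return a [PointSet-class].
#' @export
readPointsCsv <- function(path, label = "points") {
  df <- read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("CSV must have columns 'x' and 'y'", call. = FALSE)
  pointSet(as.numeric(df$x), as.numeric(df$y), label = label)
}

#' Write points or polygons as GeoJSON
#'
#' Writes a FeatureCollection; points carry a `label` property, polygons a
#' `name` property. Coordinates are in the projected working system
#' (meters), not longitude/latitude.
#'
#' @param x a [PointSet-class] or [PolygonSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeoJSON <- function(x, path) {
  feat <- function(geom, props) list(type = "Feature", geometry = geom,
                                     properties = props)
  features <- if (is(x, "PointSet")) {
    lapply(seq_len(nPoints(x)), function(i)
      feat(list(type = "Point", coordinates = c(x@coords[i, 1], x@coords[i, 2])),
           list(label = x@label)))
  } else if (is(x, "PolygonSet")) {
    lapply(seq_along(x@polygons), function(i) {
      rings <- lapply(x@polygons[[i]], function(ring) {
        closed <- rbind(ring, ring[1, ])
        lapply(seq_len(nrow(closed)), function(j) c(closed[j, 1], closed[j, 2]))
      })
      feat(list(type = "Polygon", coordinates = rings),
           list(name = x@polyNames[i]))
    })
  } else stop("writeGeoJSON() handles PointSet and PolygonSet objects",
              call. = FALSE)
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 17, null = "null")
  invisible(path)
}

#' Read a point set from GeoJSON
#'
#' @param path GeoJSON file containing Point features (a FeatureCollection,
#'   as written by [writeGeoJSON()]).
#' @param label role tag; defaults to the first feature's `label` property
#'   when present.
#' @return a [PointSet-class].
#' @export
readGeoJSONPoints <- function(path, label = NULL) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  pts <- t(vapply(feats, function(f) {
    if (!identical(f$geometry$type, "Point"))
      stop("expected Point geometries", call. = FALSE)
    as.numeric(unlist(f$geometry$coordinates))[1:2]
  }, numeric(2)))
  if (is.null(label))
    label <- if (length(feats) && !is.null(feats[[1]]$properties$label))
      feats[[1]]$properties$label else "points"
  if (!length(feats)) pts <- matrix(numeric(), 0, 2)
  pointSet(pts, label = label)
}

#' Read polygons from GeoJSON
#'
#' @param path GeoJSON file containing Polygon features.
#' @return a [PolygonSet-class]; feature `name` properties become polygon
#'   names.
#' @export
readGeoJSONPolygons <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  polys <- lapply(feats, function(f) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("expected Polygon geometries", call. = FALSE)
    lapply(f$geometry$coordinates, function(ring)
      do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))[1:2])))
  })
  nms <- vapply(seq_along(feats), function(i) {
    nm <- feats[[i]]$properties$name
    if (is.null(nm)) paste0("poly", i) else as.character(nm)
  }, character(1))
  polygonSet(polys, names = nms)
}
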