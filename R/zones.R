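## Zone extraction and effective-habitat accounting: threshold the
## path-distance surface at the human-impact and dog-foray distances and
## subtract the affected area from baseline habitat.

#' Zone mask at a path-distance threshold
#'
#' A cell is 1 exactly when its finite path distance is less than or equal
#' to `d` — the "dog zone" when `d` is the foray distance. The complementary
#' dog-free mask is the negation over finite cells. Nodata distance cells
#' stay nodata.
#'
#' @param surface a [PathDistanceSurface-class].
#' @param d threshold in meters (>= 0).
#' @return a [GridRaster-class] of kind `"mask"`.
#' @export
zoneMask <- function(surface, d) {
  stopifnot(is(surface, "PathDistanceSurface"))
  d <- .checkScalar(d, "d", min = 0)
  dist <- surface@distance
  gridRaster((dist@values <= d) + 0, dist@originX, dist@originY,
             dist@cellSize, kind = "mask")
}

#' Effective-habitat accounting
#'
#' Baseline habitat area, effective habitat I (habitat beyond the
#' human-impact distance), effective habitat II (habitat beyond the dog
#' foray distance) and the percent reduction from baseline to effective II.
#' "Beyond" is strict (`distance > threshold`), the complement of the
#' zone-mask convention `distance <= threshold`. Habitat cells whose path
#' distance is nodata (enclaves unreachable from any populated area) count
#' as beyond every threshold — unreachable by path implies unreachable by
#' dogs — and their area is reported with a warning.
#'
#' @param habitat a [GridRaster-class] habitat mask aligned with the
#'   surface.
#' @param surface a [PathDistanceSurface-class].
#' @param cfg a [ZoneConfig-class].
#' @return an [EffectiveHabitatReport-class].
#' @export
effectiveHabitat <- function(habitat, surface, cfg = zoneConfig()) {
  stopifnot(is(habitat, "GridRaster"), is(surface, "PathDistanceSurface"),
            is(cfg, "ZoneConfig"))
  if (!identical(habitat@kind, "mask"))
    stop("'habitat' must be a raster of kind 'mask'", call. = FALSE)
  .stopIfMisaligned(habitat, surface@distance, "'habitat' and the surface")
  cellKm2 <- habitat@cellSize^2 / 1e6
  hab <- !is.na(habitat@values) & habitat@values == 1
  d <- surface@distance@values
  unreachable <- hab & is.na(d)
  nodataKm2 <- sum(unreachable) * cellKm2
  if (nodataKm2 > 0)
    warning(sprintf(
      "%.1f km^2 of habitat is unreachable from any source (nodata path distance); counted as beyond every threshold",
      nodataKm2), call. = FALSE)
  beyond <- function(thr) hab & (is.na(d) | d > thr)
  effectiveHabitatReport(
    baselineKm2 = sum(hab) * cellKm2,
    effectiveIKm2 = sum(beyond(cfg@humanImpactM)) * cellKm2,
    effectiveIIKm2 = sum(beyond(cfg@forayM)) * cellKm2,
    nodataKm2 = nodataKm2)
}

#' Dog-free area and percentage from totals
#'
#' Accounting identity used for range-wide tabulation: dog-free area is
#' total minus edge-affected area, and the percentage is dog-free over
#' total.
#'
#' @param totalKm2 total area, km^2 (> 0).
#' @param edgeKm2 edge-effect (dog-zone) area, km^2; must not exceed
#'   `totalKm2`.
#' @return named list with `dogFreeKm2` and `pct`.
#' @examples
#' dogFreePercent(25710, 10240)  # 15470 km^2, 60%
#' @export
dogFreePercent <- function(totalKm2, edgeKm2) {
  totalKm2 <- .checkScalar(totalKm2, "totalKm2", min = 0, strict = TRUE)
  edgeKm2 <- .checkScalar(edgeKm2, "edgeKm2", min = 0)
  if (edgeKm2 > totalKm2)
    stop("edge-effect area exceeds total area", call. = FALSE)
  dogFree <- totalKm2 - edgeKm2
  list(dogFreeKm2 = dogFree, pct = 100 * dogFree / totalKm2)
}
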