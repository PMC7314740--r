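## Reserve prioritization: dog-zone habitat area per reserve, exact Jenks
## natural-breaks classification, and the low/moderate/high threat tiers.

#' Dog-zone habitat area per reserve
#'
#' For each reserve polygon, the area of cells that are simultaneously
#' inside the reserve, habitat, and within the foray path-distance of a
#' populated area. Habitat cells with nodata path distance are outside the
#' dog zone. A reserve entirely outside the raster extent (or containing no
#' qualifying cell) scores 0 with a warning in the former case.
#'
#' @param reserves a non-empty [PolygonSet-class] of reserve boundaries.
#' @param habitat a [GridRaster-class] habitat mask aligned with the
#'   surface.
#' @param surface a [PathDistanceSurface-class].
#' @param cfg a [ZoneConfig-class] supplying the foray distance.
#' @return data.frame with columns `reserve_id` and `dog_zone_habitat_km2`.
#' @export
dogZoneHabitatByReserve <- function(reserves, habitat, surface,
                                    cfg = zoneConfig()) {
  stopifnot(is(reserves, "PolygonSet"), is(habitat, "GridRaster"),
            is(surface, "PathDistanceSurface"), is(cfg, "ZoneConfig"))
  if (!nPolygons(reserves))
    stop("'reserves' must contain at least one polygon", call. = FALSE)
  .stopIfMisaligned(habitat, surface@distance, "'habitat' and the surface")
  cellKm2 <- habitat@cellSize^2 / 1e6
  d <- surface@distance@values
  inZone <- !is.na(d) & d <= cfg@forayM
  hab <- !is.na(habitat@values) & habitat@values == 1
  ext <- rasterExtent(habitat)
  areas <- vapply(seq_len(nPolygons(reserves)), function(i) {
    one <- new("PolygonSet", polygons = reserves@polygons[i],
               polyNames = reserves@polyNames[i])
    bb <- do.call(rbind, unlist(one@polygons, recursive = FALSE))
    if (max(bb[, 1]) < ext["xmin"] || min(bb[, 1]) > ext["xmax"] ||
        max(bb[, 2]) < ext["ymin"] || min(bb[, 2]) > ext["ymax"]) {
      warning("reserve '", one@polyNames, "' lies entirely outside the ",
              "raster extent; area set to 0", call. = FALSE)
      return(0)
    }
    inRes <- rasterizePolygons(one, habitat)@values == 1
    sum(inRes & hab & inZone) * cellKm2
  }, numeric(1))
  data.frame(reserve_id = reserves@polyNames,
             dog_zone_habitat_km2 = areas,
             stringsAsFactors = FALSE)
}

# Within-class sum of squared deviations of sorted[i..j], from prefix sums.
.makeSSD <- function(sorted) {
  s1 <- c(0, cumsum(sorted))
  s2 <- c(0, cumsum(sorted^2))
  function(i, j) {
    n <- j - i + 1
    (s2[j + 1] - s2[i]) - (s1[j + 1] - s1[i])^2 / n
  }
}

#' Jenks natural breaks (Fisher's exact dynamic program)
#'
#' Globally optimal partition of the values into `k` contiguous classes (in
#' sorted order) minimizing the total within-class sum of squared
#' deviations — equivalently, maximizing the variance between classes. This
#' is the exact optimization, not the iterative heuristic. Ties between
#' equally optimal partitions are broken by preferring the partition whose
#' first break is smallest, then recursively (the lexicographically
#' smallest boundary vector).
#'
#' @param values numeric vector, `length(values) >= k`.
#' @param k number of classes (>= 1).
#' @return a [JenksResult-class]. Breaks are the midpoints between the
#'   adjacent class-edge values; `assignment` gives the 1-based class per
#'   input value in input order; `gvf = 1 - SSD_within / SSD_total` (1 when
#'   all values are equal).
#' @examples
#' jenksBreaks(c(1, 2, 3, 100, 101, 102), k = 2)
#' @export
jenksBreaks <- function(values, k) {
  if (anyNA(values) || !all(is.finite(values)))
    stop("'values' must be finite and free of NA", call. = FALSE)
  n <- length(values)
  k <- .checkCount(k, "k", min = 1L)
  if (k > n)
    stop("k (", k, ") may not exceed the number of values (", n, ")",
         call. = FALSE)
  ord <- order(values)
  v <- values[ord]
  ssd <- .makeSSD(v)

  # suffix[m, i]: minimal cost of partitioning v[i..n] into m classes
  suffix <- matrix(Inf, k, n + 1L)
  suffix[, n + 1L] <- Inf
  for (i in n:1) suffix[1L, i] <- ssd(i, n)
  if (k > 1L) for (m in 2:k) for (i in 1:(n - m + 1L)) {
    ends <- i:(n - m + 1L)
    costs <- vapply(ends, function(b) ssd(i, b) + suffix[m - 1L, b + 1L],
                    numeric(1))
    suffix[m, i] <- min(costs)
  }
  total <- suffix[k, 1L]

  # reconstruct boundaries greedily from the front: smallest end index of
  # the current class that still achieves the optimum
  bounds <- integer(0)
  i <- 1L
  if (k > 1L) for (m in k:2) {
    ends <- i:(n - m + 1L)
    costs <- vapply(ends, function(b) ssd(i, b) + suffix[m - 1L, b + 1L],
                    numeric(1))
    target <- suffix[m, i]
    tol <- 1e-9 * max(1, abs(target))
    b <- ends[which(costs <= target + tol)[1L]]
    bounds <- c(bounds, b)
    i <- b + 1L
  }

  classOfSorted <- findInterval(seq_len(n) - 1L, bounds) + 1L
  assignment <- integer(n)
  assignment[ord] <- classOfSorted
  breaks <- vapply(bounds, function(b) (v[b] + v[b + 1L]) / 2, numeric(1))
  ssdTotal <- ssd(1L, n)
  gvf <- if (ssdTotal > 0) 1 - total / ssdTotal else 1
  new("JenksResult", breaks = breaks, gvf = max(0, min(1, gvf)),
      assignment = assignment, k = k, withinSSD = total)
}

#' Classify a reserve's dog-zone habitat area into a threat tier
#'
#' Low if the area is below `lowBreak`, moderate from `lowBreak` up to (but
#' not including) `highBreak`, high at or above `highBreak`. The boundary
#' value `highBreak` itself classifies as high — the conservative choice
#' for a threat ranking. Default breaks (50 and 165 km^2) are the
#' natural-breaks tiers of the range-wide analysis; alternatively re-derive
#' breaks from a fresh value list with [jenksBreaks()].
#'
#' @param dogZoneHabitatKm2 area(s) in km^2 (vectorized).
#' @param lowBreak,highBreak tier boundaries in km^2.
#' @return factor with levels `low`, `moderate`, `high`.
#' @examples
#' classifyThreat(c(0, 60, 367))
#' @export
classifyThreat <- function(dogZoneHabitatKm2, lowBreak = 50,
                           highBreak = 165) {
  if (anyNA(dogZoneHabitatKm2) || any(dogZoneHabitatKm2 < 0))
    stop("areas must be non-negative and free of NA", call. = FALSE)
  if (!(lowBreak >= 0 && highBreak >= lowBreak))
    stop("breaks must satisfy 0 <= lowBreak <= highBreak", call. = FALSE)
  out <- ifelse(dogZoneHabitatKm2 < lowBreak, "low",
                ifelse(dogZoneHabitatKm2 < highBreak, "moderate", "high"))
  factor(out, levels = c("low", "moderate", "high"))
}

#' Rank reserves by dog threat
#'
#' Combines [dogZoneHabitatByReserve()] with either the fixed tier breaks
#' or breaks re-derived from the value list via [jenksBreaks()] with k = 3.
#'
#' @param reserveAreas data.frame as returned by
#'   [dogZoneHabitatByReserve()].
#' @param breakMode `"fixed"` (use `lowBreak`/`highBreak`) or `"jenks"`
#'   (re-derive two breaks from the areas; requires >= 3 reserves).
#' @param lowBreak,highBreak fixed tier boundaries, km^2.
#' @return the input data.frame with a `category` column, ordered by
#'   decreasing area.
#' @export
rankReserveThreat <- function(reserveAreas, breakMode = c("fixed", "jenks"),
                              lowBreak = 50, highBreak = 165) {
  breakMode <- match.arg(breakMode)
  stopifnot(is.data.frame(reserveAreas),
            all(c("reserve_id", "dog_zone_habitat_km2") %in%
                  names(reserveAreas)))
  a <- reserveAreas$dog_zone_habitat_km2
  if (breakMode == "jenks") {
    jb <- jenksBreaks(a, k = min(3L, length(a)))
    if (length(jb@breaks) < 2L)
      stop("need at least 3 distinct reserves to re-derive Jenks breaks",
           call. = FALSE)
    lowBreak <- jb@breaks[1]; highBreak <- jb@breaks[2]
  }
  out <- reserveAreas
  out$category <- classifyThreat(a, lowBreak, highBreak)
  out[order(-out$dog_zone_habitat_km2), , drop = FALSE]
}
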