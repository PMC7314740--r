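## Synthetic landscapes: terrain with carved valleys, villages biased to
## low elevations, an elevation-band habitat mask with reserve polygons,
## and occurrence points sampled under a logistic distance-avoidance
## response. The generator exists so the full pipeline runs and is tested
## without the sensitive occurrence data real analyses depend on.

#' LandscapeConfig: parameters of the synthetic landscape
#'
#' Defaults describe a 20 x 20 km mountainous landscape: 200 x 200 cells at
#' 100 m, 2,000 m of relief with 3 carved valleys, 12 villages of 20-60
#' houses scattered 300 m around their centers at low elevations, habitat
#' in the 150-1,000 m elevation band (the forested slopes flanking the settled valleys and the incised hinterland valley), and 3 reserves.
#'
#' @slot seed integer master seed; each generation stage draws from its own
#'   derived stream so changing one stage's parameters does not perturb the
#'   others.
#' @slot nRows,nCols grid dimensions.
#' @slot cellSizeM cell size, m.
#' @slot reliefM peak-to-valley elevation amplitude, m.
#' @slot nValleys number of carved linear valleys.
#' @slot nVillages number of villages.
#' @slot housesPerVillage integer range (min, max) of houses per village.
#' @slot villageSpreadM scatter (Gaussian SD, m) of houses around a village
#'   center.
#' @slot habitatBandM elevation band (low, high) defining habitat, m.
#' @slot nReserves number of reserve polygons.
#'
#' @seealso [landscapeConfig()]
#' @exportClass LandscapeConfig
setClass("LandscapeConfig",
  representation(
    seed = "integer", nRows = "integer", nCols = "integer",
    cellSizeM = "numeric", reliefM = "numeric", nValleys = "integer",
    nVillages = "integer", housesPerVillage = "integer",
    villageSpreadM = "numeric", habitatBandM = "numeric",
    nReserves = "integer"
  )
)

setValidity("LandscapeConfig", function(object) {
  msg <- character()
  if (object@nRows < 1L || object@nCols < 1L)
    msg <- c(msg, "grid must have at least one row and column")
  if (object@cellSizeM <= 0) msg <- c(msg, "'cellSizeM' must be positive")
  if (object@reliefM < 0) msg <- c(msg, "'reliefM' must be non-negative")
  if (any(c(object@nValleys, object@nVillages, object@nReserves) < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (length(object@housesPerVillage) != 2L ||
      any(object@housesPerVillage < 0L) ||
      object@housesPerVillage[1] > object@housesPerVillage[2])
    msg <- c(msg, "'housesPerVillage' must be an ascending (min, max) pair")
  if (length(object@habitatBandM) != 2L ||
      object@habitatBandM[1] >= object@habitatBandM[2])
    msg <- c(msg, "'habitatBandM' must be an ascending (low, high) pair")
  if (length(msg)) msg else TRUE
})

#' Construct a LandscapeConfig
#'
#' @param seed master seed.
#' @param nRows,nCols grid dimensions (default 200 x 200).
#' @param cellSizeM cell size in meters (default 100).
#' @param reliefM peak-to-valley amplitude in meters (default 2000).
#' @param nValleys carved valleys (default 3).
#' @param nVillages villages (default 12).
#' @param housesPerVillage (min, max) houses per village (default 20-60).
#' @param villageSpreadM house scatter SD in meters (default 300).
#' @param habitatBandM habitat elevation band in meters (default 150-1000).
#' @param nReserves reserve polygons (default 3).
#' @return a [LandscapeConfig-class].
#' @export
landscapeConfig <- function(seed = 1L, nRows = 200L, nCols = 200L,
                            cellSizeM = 100, reliefM = 2000, nValleys = 3L,
                            nVillages = 12L, housesPerVillage = c(20L, 60L),
                            villageSpreadM = 300, habitatBandM = c(150, 1000),
                            nReserves = 3L) {
  new("LandscapeConfig", seed = as.integer(seed), nRows = as.integer(nRows),
      nCols = as.integer(nCols), cellSizeM = as.numeric(cellSizeM),
      reliefM = as.numeric(reliefM), nValleys = as.integer(nValleys),
      nVillages = as.integer(nVillages),
      housesPerVillage = as.integer(housesPerVillage),
      villageSpreadM = as.numeric(villageSpreadM),
      habitatBandM = as.numeric(habitatBandM),
      nReserves = as.integer(nReserves))
}

#' OccurrenceConfig: scenario for simulated occurrence locations
#'
#' The `many_dogs` scenario uses an avoidance midpoint at the dog foray
#' distance (10,900 m) — occurrences concentrate in the dog-free zone; the
#' `few_dogs` scenario uses the human-impact distance (1,920 m) — the only
#' avoidance is of the immediate human footprint; `null` is uniform use of
#' habitat.
#'
#' @slot seed integer seed.
#' @slot n number of occurrences.
#' @slot scenario one of `"many_dogs"`, `"few_dogs"`, `"null"`.
#' @slot thetaM avoidance midpoint, m.
#' @slot sM avoidance softness, m (> 0).
#'
#' @seealso [occurrenceConfig()]
#' @exportClass OccurrenceConfig
setClass("OccurrenceConfig",
  representation(seed = "integer", n = "integer", scenario = "character",
                 thetaM = "numeric", sM = "numeric")
)

setValidity("OccurrenceConfig", function(object) {
  msg <- character()
  if (!(object@scenario %in% c("many_dogs", "few_dogs", "null")))
    msg <- c(msg, "'scenario' must be many_dogs, few_dogs or null")
  if (object@n < 0L) msg <- c(msg, "'n' must be non-negative")
  if (object@sM <= 0) msg <- c(msg, "'sM' must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an OccurrenceConfig
#'
#' @param scenario `"many_dogs"`, `"few_dogs"` or `"null"`.
#' @param n number of occurrences (default 46, a typical reserve-level
#'   census sample).
#' @param seed integer seed.
#' @param thetaM avoidance midpoint, m; defaults to 10,900 for `many_dogs`
#'   and 1,920 for `few_dogs` (ignored for `null`).
#' @param sM avoidance softness, m (default 1,000).
#' @return an [OccurrenceConfig-class].
#' @export
occurrenceConfig <- function(scenario = c("many_dogs", "few_dogs", "null"),
                             n = 46L, seed = 1L, thetaM = NULL, sM = 1000) {
  scenario <- match.arg(scenario)
  if (is.null(thetaM))
    thetaM <- switch(scenario, many_dogs = 10900, few_dogs = 1920, 0)
  new("OccurrenceConfig", seed = as.integer(seed), n = as.integer(n),
      scenario = scenario, thetaM = as.numeric(thetaM), sM = as.numeric(sM))
}

# Normalized cell-center coordinate grids (u east, v north in [0, 1]).
.unitGrids <- function(nr, nc) {
  list(u = matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc),
       v = matrix(rep((nr - seq_len(nr) + 0.5) / nr, times = nc), nr, nc))
}

# Random dihedral transform of the unit coordinates: 8 mirror/transpose
# variants so the fixed cross-section profile can face any direction.
.dihedral <- function(g, code) {
  u <- g$u; v <- g$v
  if (code %% 2L == 1L) u <- 1 - u
  if ((code %/% 2L) %% 2L == 1L) v <- 1 - v
  if ((code %/% 4L) %% 2L == 1L) { tmp <- u; u <- v; v <- tmp }
  list(u = u, v = v)
}

#' Generate synthetic terrain
#'
#' Emulates the cross-section of a settled mountain-front landscape: a
#' low foreland carrying `nValleys - 1` parallel trunk valleys (where
#' settlement concentrates), terrain rising to a high transverse range
#' near three-quarters of the way across, and a remote hinterland valley
#' behind the range. Low-frequency sinusoidal roughness and jittered
#' valley positions are superimposed, the whole section faces a
#' seed-random direction (one of eight mirror/transpose orientations), and
#' the result is rescaled so the elevation range equals `reliefM` exactly
#' (flat when `reliefM` is 0). Bit-identical for a fixed seed.
#'
#' @param cfg a [LandscapeConfig-class].
#' @return a [GridRaster-class] of kind `"elevation_m"` whose north-west
#'   origin is (0, nRows * cellSizeM).
#' @export
generateTerrain <- function(cfg = landscapeConfig()) {
  stopifnot(is(cfg, "LandscapeConfig"))
  validObject(cfg)
  nr <- cfg@nRows; nc <- cfg@nCols
  z <- .withSeed(cfg@seed, {
    g <- .dihedral(.unitGrids(nr, nc), sample.int(8L, 1L) - 1L)
    tn <- g$u # transverse coordinate: 0 = settled front, 1 = far edge
    # regional cross-section (meters, before the final rescale): a gentle
    # foreland rising 150 -> 600 m over the first 60%, a steep escarpment
    # climbing 1,400 m to the range crest at ~77%, and a hinterland
    # plateau ~750 m below the crest
    ridgePos <- 0.77 + runif(1, -0.03, 0.03)
    z <- 150 + 450 * pmin(tn / 0.6, 1)^1.5 +
      1400 * pmax(0, pmin((tn - 0.6) / (ridgePos - 0.6), 1))^2 -
      750 * pmax(0, pmin((tn - ridgePos) / 0.08, 1))
    for (k in 1:6) {
      fx <- runif(1, -2.5, 2.5); fy <- runif(1, -2.5, 2.5)
      ph <- runif(1, 0, 2 * pi)
      z <- z + 120 * sin(2 * pi * (fx * g$u + fy * g$v) + ph) / k
    }
    if (cfg@nValleys > 0L) {
      # settled trunk valleys spread across the foreland, one remote
      # valley incised into the hinterland plateau
      nFore <- max(1L, cfg@nValleys - 1L)
      lo <- seq(0.05, 0.45, length.out = nFore + 1L)
      tv <- vapply(seq_len(nFore), function(i) runif(1, lo[i], lo[i + 1L]),
                   numeric(1))
      depth <- runif(nFore, 250, 400)
      if (cfg@nValleys > 1L) {
        tv <- c(tv, 0.91 + runif(1, -0.02, 0.02))
        depth <- c(depth, runif(1, 680, 820))
      }
      for (i in seq_along(tv)) {
        width <- if (i == length(tv) && cfg@nValleys > 1L)
          runif(1, 0.03, 0.05) else runif(1, 0.02, 0.04)
        z <- z - depth[i] * exp(-(tn - tv[i])^2 / (2 * width^2))
      }
    }
    z
  })
  rng <- range(z)
  z <- if (cfg@reliefM > 0 && diff(rng) > 0)
    (z - rng[1]) / diff(rng) * cfg@reliefM
  else matrix(0, nr, nc)
  gridRaster(z, 0, nr * cfg@cellSizeM, cfg@cellSizeM, kind = "elevation_m")
}

#' Place residences in settled valleys
#'
#' Village centers are sampled among cells in the lowest elevation decile —
#' the valley floors, where settlements follow roads and rivers — with
#' sampling weight decaying exponentially in elevation; after the first
#' village, weight also prefers sites about 3.2 km from the nearest
#' existing village, so villages string along shared valley roads — beads
#' on a chain — instead of scattering over the whole landscape.
#' Houses scatter around each center with a Gaussian of SD
#' `villageSpreadM`. Reproducible for a fixed master seed; this stage uses
#' its own derived stream.
#'
#' @param dem a [GridRaster-class] elevation raster.
#' @param cfg a [LandscapeConfig-class].
#' @return a [PointSet-class] labelled `"residences"`.
#' @export
placeResidences <- function(dem, cfg = landscapeConfig()) {
  stopifnot(is(dem, "GridRaster"), is(cfg, "LandscapeConfig"))
  if (cfg@nVillages == 0L) return(pointSet(label = "residences"))
  z <- dem@values
  .withSeed(cfg@seed + 1L, {
    q10 <- quantile(z, 0.10, na.rm = TRUE, names = FALSE)
    cand <- which(!is.na(z) & z <= q10)
    r <- ((cand - 1L) %% nrow(z)) + 1L
    c <- ((cand - 1L) %/% nrow(z)) + 1L
    px <- dem@originX + (c - 0.5) * dem@cellSize
    py <- dem@originY - (r - 0.5) * dem@cellSize
    zr <- diff(range(z, na.rm = TRUE))
    wElev <- if (zr > 0) exp(-15 * (z[cand] - min(z, na.rm = TRUE)) / zr)
             else rep(1, length(cand))
    spacing <- 3200; spacingSd <- 1200
    centers <- integer(0)
    for (i in seq_len(min(cfg@nVillages, length(cand)))) {
      w <- wElev
      if (length(centers)) {
        dNear <- Reduce(pmin, lapply(centers, function(a)
          sqrt((px - px[a])^2 + (py - py[a])^2)))
        w <- w * exp(-((dNear - spacing) / spacingSd)^2 / 2)
        w[centers] <- 0
      }
      if (sum(w) <= 0) w <- wElev
      centers <- c(centers, sample.int(length(cand), 1L, prob = w))
    }
    xs <- numeric(0); ys <- numeric(0)
    for (i in centers) {
      nh <- sample(cfg@housesPerVillage[1]:cfg@housesPerVillage[2], 1L)
      xs <- c(xs, px[i] + rnorm(nh, 0, cfg@villageSpreadM))
      ys <- c(ys, py[i] + rnorm(nh, 0, cfg@villageSpreadM))
    }
    pointSet(xs, ys, label = "residences")
  })
}

#' Habitat mask and reserve polygons
#'
#' Habitat is the elevation band `habitatBandM` (inclusive), mirroring how
#' montane habitat tracks the elevation range of understory forage.
#' Reserves are rectangles with jittered vertices anchored on habitat cells
#' chosen to be far apart (greedy farthest-point), each guaranteed to
#' contain at least one habitat cell; rectangle size shrinks if needed to
#' keep reserves disjoint.
#'
#' @param dem a [GridRaster-class] elevation raster.
#' @param cfg a [LandscapeConfig-class].
#' @return list with elements `habitat` (a mask [GridRaster-class]) and
#'   `reserves` (a [PolygonSet-class]).
#' @export
generateHabitatAndReserves <- function(dem, cfg = landscapeConfig()) {
  stopifnot(is(dem, "GridRaster"), is(cfg, "LandscapeConfig"))
  z <- dem@values
  hab <- (!is.na(z) & z >= cfg@habitatBandM[1] & z <= cfg@habitatBandM[2]) + 0
  hab[is.na(z)] <- NA
  habitat <- gridRaster(hab, dem@originX, dem@originY, dem@cellSize,
                        kind = "mask")
  if (!any(hab == 1, na.rm = TRUE)) {
    warning("habitat band excludes all cells: habitat mask is empty",
            call. = FALSE)
    return(list(habitat = habitat,
                reserves = polygonSet(list(), character(0))))
  }
  if (cfg@nReserves == 0L)
    return(list(habitat = habitat,
                reserves = polygonSet(list(), character(0))))
  ones <- which(hab == 1)
  r <- ((ones - 1L) %% nrow(z)) + 1L
  c <- ((ones - 1L) %/% nrow(z)) + 1L
  px <- dem@originX + (c - 0.5) * dem@cellSize
  py <- dem@originY - (r - 0.5) * dem@cellSize
  .withSeed(cfg@seed + 2L, {
    n <- min(cfg@nReserves, length(ones))
    anchors <- sample.int(length(ones), 1L)
    while (length(anchors) < n) {
      d2min <- Reduce(pmin, lapply(anchors, function(a)
        (px - px[a])^2 + (py - py[a])^2))
      anchors <- c(anchors, which.max(d2min))
    }
    ext <- rasterExtent(dem)
    half <- 0.15 * min(ext["xmax"] - ext["xmin"], ext["ymax"] - ext["ymin"])
    if (n > 1L) {
      dmin <- min(vapply(seq_len(n - 1L), function(i)
        min(sqrt((px[anchors[(i + 1L):n]] - px[anchors[i]])^2 +
                 (py[anchors[(i + 1L):n]] - py[anchors[i]])^2)),
        numeric(1)))
      half <- max(dem@cellSize, min(half, 0.45 * dmin))
    }
    polys <- lapply(anchors, function(a) {
      # octagonal outline: rectangle corners + edge midpoints, jittered
      ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
      vx <- px[a] + half * pmax(-1, pmin(1, sqrt(2) * cos(ang))) +
        runif(8, -0.08, 0.08) * half
      vy <- py[a] + half * pmax(-1, pmin(1, sqrt(2) * sin(ang))) +
        runif(8, -0.08, 0.08) * half
      cbind(vx, vy)
    })
    list(habitat = habitat,
         reserves = polygonSet(polys,
                               names = paste0("reserve", seq_len(n))))
  })
}

#' Simulate occurrence locations under distance avoidance
#'
#' Habitat cells with finite path distance are sampled with replacement
#' with probability proportional to the logistic avoidance weight
#' `w(d) = 1 / (1 + exp(-(d - thetaM) / sM))` (uniform for the `null`
#' scenario), and each occurrence is jittered uniformly within its cell.
#' Multiple occurrences may share a cell, as field sign locations cluster.
#'
#' @param surface a [PathDistanceSurface-class].
#' @param habitat a [GridRaster-class] habitat mask aligned with the
#'   surface.
#' @param cfg an [OccurrenceConfig-class].
#' @return a [PointSet-class] labelled `"occurrences"`.
#' @export
simulateOccurrences <- function(surface, habitat, cfg = occurrenceConfig()) {
  stopifnot(is(surface, "PathDistanceSurface"), is(habitat, "GridRaster"),
            is(cfg, "OccurrenceConfig"))
  validObject(cfg)
  .stopIfMisaligned(habitat, surface@distance, "'habitat' and the surface")
  if (cfg@n == 0L) return(pointSet(label = "occurrences"))
  d <- surface@distance@values
  elig <- which(!is.na(habitat@values) & habitat@values == 1 & !is.na(d))
  if (!length(elig))
    stop("no habitat cells with finite path distance to sample from",
         call. = FALSE)
  w <- if (cfg@scenario == "null") rep(1, length(elig))
       else plogis((d[elig] - cfg@thetaM) / cfg@sM)
  if (sum(w) <= 0)
    stop("occurrence sampling failed: all avoidance weights are zero",
         call. = FALSE)
  .withSeed(cfg@seed, {
    cells <- elig[sample.int(length(elig), cfg@n, replace = TRUE, prob = w)]
    r <- ((cells - 1L) %% nrow(d)) + 1L
    c <- ((cells - 1L) %/% nrow(d)) + 1L
    cs <- habitat@cellSize
    x <- habitat@originX + (c - 1L + runif(cfg@n)) * cs
    y <- habitat@originY - (r - 1L + runif(cfg@n)) * cs
    pointSet(x, y, label = "occurrences")
  })
}
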