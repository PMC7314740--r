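## End-to-end orchestration: density -> populated mask -> path distance ->
## zones -> effective habitat -> use vs availability -> prioritization,
## with optional plain-text outputs for every intermediate product.

.stage <- function(name, expr, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  if (verbose)
    message(sprintf("[dogedge] %-14s %6.2f s", name,
                    proc.time()[["elapsed"]] - t0))
  out
}

#' Run the dog edge-effect pipeline end to end
#'
#' Executes housing density, populated-area masking, path distance, zone
#' extraction, effective-habitat accounting, use-versus-availability
#' comparison and reserve threat ranking in sequence. Inputs are either a
#' synthetic landscape (the default) or file paths to real data layers;
#' exactly one of the two modes is active.
#'
#' Conservation identities are asserted on every run: dog-zone plus
#' dog-free area equals the total finite-distance area, and baseline
#' habitat equals dog-zone habitat plus effective habitat II.
#'
#' @param landscape a [LandscapeConfig-class] (synthetic mode).
#' @param occurrences an [OccurrenceConfig-class] (synthetic mode).
#' @param density a [DensityConfig-class].
#' @param zones a [ZoneConfig-class].
#' @param nAvailable number of random available locations (default 100).
#' @param availSeed seed for availability sampling; default derives from
#'   the landscape seed.
#' @param breakMode `"fixed"` (50/165 km^2 tiers) or `"jenks"` (re-derive).
#' @param lowBreak,highBreak fixed tier boundaries, km^2.
#' @param fitModel also fit the logistic avoidance model (off by default;
#'   it is an extension beyond the headline comparison).
#' @param inputs real-data mode: named list of file paths `dem` (ASCII
#'   grid), `residences` (CSV or GeoJSON points), `habitat` (ASCII grid
#'   mask), `reserves` (GeoJSON polygons) and optionally `occurrences`
#'   (CSV/GeoJSON points). Supplying this disables the synthetic
#'   generators.
#' @param outDir directory for intermediate rasters (ASCII grid), point
#'   sets (CSV), reserves (GeoJSON), the key/value report and the threat
#'   CSV; `NULL` writes nothing.
#' @param verbose log stage timings.
#' @return a list (invisible when writing to `outDir`) with elements
#'   `effective` ([EffectiveHabitatReport-class]), `useAvailability`
#'   ([UseAvailabilityResult-class]), `threat` (ranked data.frame),
#'   `totals` (dog-zone/dog-free accounting), `maxDistanceM`, `avoidance`
#'   (when `fitModel`), and the generated/loaded data layers under `data`.
#' @examples
#' \donttest{
#' rep <- runPipeline(landscape = landscapeConfig(seed = 7, nRows = 80,
#'                                                nCols = 80))
#' rep$effective
#' }
#' @export
runPipeline <- function(landscape = landscapeConfig(),
                        occurrences = occurrenceConfig(),
                        density = densityConfig(),
                        zones = zoneConfig(),
                        nAvailable = 100L,
                        availSeed = NULL,
                        breakMode = c("fixed", "jenks"),
                        lowBreak = 50, highBreak = 165,
                        fitModel = FALSE,
                        inputs = NULL,
                        outDir = NULL,
                        verbose = FALSE) {
  breakMode <- match.arg(breakMode)
  nAvailable <- .checkCount(nAvailable, "nAvailable")
  synthetic <- is.null(inputs)
  if (is.null(availSeed))
    availSeed <- if (synthetic) landscape@seed + 3L else 1L

  if (synthetic) {
    dem <- .stage("terrain", generateTerrain(landscape), verbose)
    residences <- .stage("residences", placeResidences(dem, landscape),
                         verbose)
    hr <- .stage("habitat", generateHabitatAndReserves(dem, landscape),
                 verbose)
    habitat <- hr$habitat
    reserves <- hr$reserves
    occPts <- NULL # simulated after the surface exists
  } else {
    need <- c("dem", "residences", "habitat", "reserves")
    if (!all(need %in% names(inputs)))
      stop("real-data mode needs input paths: ",
           paste(need, collapse = ", "), call. = FALSE)
    readPts <- function(path, label) {
      if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE))
        readGeoJSONPoints(path, label = label)
      else readPointsCsv(path, label = label)
    }
    dem <- .stage("read dem", readAsciiGrid(inputs$dem, "elevation_m"),
                  verbose)
    residences <- .stage("read residences",
                         readPts(inputs$residences, "residences"), verbose)
    habitat <- .stage("read habitat", readAsciiGrid(inputs$habitat, "mask"),
                      verbose)
    reserves <- .stage("read reserves",
                       readGeoJSONPolygons(inputs$reserves), verbose)
    occPts <- if (!is.null(inputs$occurrences))
      .stage("read occurrences", readPts(inputs$occurrences, "occurrences"),
             verbose)
  }

  dens <- .stage("density",
                 housingDensitySurface(residences, dem, density), verbose)
  popMask <- .stage("populated mask", populatedMask(dens, density), verbose)
  surface <- .stage("path distance", surfacePathDistance(dem, popMask),
                    verbose)
  dogZone <- .stage("zones", zoneMask(surface, zones@forayM), verbose)
  effective <- .stage("effective habitat",
                      effectiveHabitat(habitat, surface, zones), verbose)

  # dog-zone / dog-free accounting over all finite-distance cells
  dvals <- distanceRaster(surface)@values
  cellKm2 <- cellSize(dem)^2 / 1e6
  totalKm2 <- sum(!is.na(dvals)) * cellKm2
  dogZoneKm2 <- maskAreaKm2(dogZone)
  totals <- list(totalKm2 = totalKm2, dogZoneKm2 = dogZoneKm2,
                 dogFreeKm2 = totalKm2 - dogZoneKm2,
                 pctDogFree = if (totalKm2 > 0)
                   100 * (totalKm2 - dogZoneKm2) / totalKm2 else NA_real_)

  if (synthetic)
    occPts <- .stage("occurrences",
                     simulateOccurrences(surface, habitat, occurrences),
                     verbose)

  ua <- avoid <- NULL
  if (!is.null(occPts) && nPoints(occPts) > 0L) {
    availPts <- .stage("available",
                       sampleAvailable(habitat, nAvailable, availSeed),
                       verbose)
    usedD <- extractValuesAtPoints(distanceRaster(surface), occPts)
    availD <- extractValuesAtPoints(distanceRaster(surface), availPts)
    if (anyNA(usedD) || anyNA(availD))
      stop("pipeline stage 'use vs availability' failed: points fell on ",
           "nodata distance cells", call. = FALSE)
    ua <- .stage("use vs availability",
                 summarizeShift(usedD, availD, zones), verbose)
    if (fitModel)
      avoid <- .stage("avoidance fit", fitAvoidance(usedD, availD), verbose)
  } else availPts <- NULL

  threat <- NULL
  if (nPolygons(reserves) > 0L) {
    byRes <- .stage("prioritization",
                    dogZoneHabitatByReserve(reserves, habitat, surface,
                                            zones), verbose)
    threat <- rankReserveThreat(byRes, breakMode, lowBreak, highBreak)
  }

  # conservation identities; abort rather than report inconsistent areas
  tol <- 1e-6 * max(1, totalKm2)
  stopifnot(abs(totals$dogZoneKm2 + totals$dogFreeKm2 - totals$totalKm2) < tol)
  habDogZoneKm2 <- sum(!is.na(habitat@values) & habitat@values == 1 &
                         !is.na(dvals) & dvals <= zones@forayM) * cellKm2
  stopifnot(abs(habDogZoneKm2 + effective@effectiveIIKm2 -
                  effective@baselineKm2) < tol)

  report <- list(
    mode = if (synthetic) "synthetic" else "files",
    params = list(densityThresholdPerKm2 = density@thresholdPerKm2,
                  windowRadiusM = density@windowRadiusM,
                  humanImpactM = zones@humanImpactM, forayM = zones@forayM,
                  nAvailable = nAvailable, breakMode = breakMode),
    effective = effective,
    totals = totals,
    habitatDogZoneKm2 = habDogZoneKm2,
    maxDistanceM = maxFiniteDistance(surface),
    useAvailability = ua,
    avoidance = avoid,
    threat = threat,
    data = list(dem = dem, residences = residences, habitat = habitat,
                reserves = reserves, densitySurface = dens,
                populated = popMask, surface = surface, dogZone = dogZone,
                occurrences = occPts, available = availPts))

  if (!is.null(outDir)) {
    .writePipelineOutputs(report, outDir)
    return(invisible(report))
  }
  report
}

# Write every intermediate layer plus the report in plain-text formats.
.writePipelineOutputs <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  d <- report$data
  writeAsciiGrid(d$dem, p("dem.asc"))
  writeAsciiGrid(d$densitySurface, p("density.asc"))
  writeAsciiGrid(d$populated, p("populated.asc"))
  writeAsciiGrid(distanceRaster(d$surface), p("pathdist.asc"))
  writeAsciiGrid(d$dogZone, p("dogzone.asc"))
  writeAsciiGrid(d$habitat, p("habitat.asc"))
  writePointsCsv(d$residences, p("residences.csv"))
  if (!is.null(d$occurrences)) writePointsCsv(d$occurrences,
                                              p("occurrences.csv"))
  if (!is.null(d$available)) writePointsCsv(d$available, p("available.csv"))
  if (nPolygons(d$reserves)) writeGeoJSON(d$reserves, p("reserves.geojson"))
  if (!is.null(report$threat)) {
    th <- report$threat
    th$dog_zone_habitat_km2 <- sprintf("%.6f", th$dog_zone_habitat_km2)
    write.csv(th, p("threat.csv"), row.names = FALSE, quote = FALSE)
  }
  writeLines(reportLines(report), p("report.txt"))
  invisible(outDir)
}

#' Key/value lines of a pipeline report
#'
#' Deterministic plain-text rendering of the machine-readable report:
#' identical configurations and seeds produce byte-identical output.
#'
#' @param report a list as returned by [runPipeline()].
#' @return character vector of `section.key = value` lines.
#' @export
reportLines <- function(report) {
  num <- function(x) sprintf("%.6f", x)
  ln <- c(sprintf("mode = %s", report$mode),
          sprintf("params.density_threshold_per_km2 = %s",
                  num(report$params$densityThresholdPerKm2)),
          sprintf("params.window_radius_m = %s",
                  num(report$params$windowRadiusM)),
          sprintf("params.human_impact_m = %s", num(report$params$humanImpactM)),
          sprintf("params.foray_m = %s", num(report$params$forayM)),
          sprintf("params.n_available = %d", report$params$nAvailable),
          sprintf("params.break_mode = %s", report$params$breakMode),
          sprintf("habitat.baseline_km2 = %s", num(report$effective@baselineKm2)),
          sprintf("habitat.effective_I_km2 = %s",
                  num(report$effective@effectiveIKm2)),
          sprintf("habitat.effective_II_km2 = %s",
                  num(report$effective@effectiveIIKm2)),
          sprintf("habitat.reduction_II_pct = %s",
                  num(report$effective@reductionIIPct)),
          sprintf("habitat.dog_zone_km2 = %s", num(report$habitatDogZoneKm2)),
          sprintf("zone.total_km2 = %s", num(report$totals$totalKm2)),
          sprintf("zone.dog_zone_km2 = %s", num(report$totals$dogZoneKm2)),
          sprintf("zone.dog_free_km2 = %s", num(report$totals$dogFreeKm2)),
          sprintf("zone.pct_dog_free = %s", num(report$totals$pctDogFree)),
          sprintf("surface.max_distance_m = %s", num(report$maxDistanceM)))
  ua <- report$useAvailability
  if (!is.null(ua))
    ln <- c(ln,
            sprintf("use.n_used = %d", ua@nUsed),
            sprintf("use.n_available = %d", ua@nAvailable),
            sprintf("use.mean_used_km = %s", num(ua@meanUsedKm)),
            sprintf("use.mean_avail_km = %s", num(ua@meanAvailKm)),
            sprintf("use.sd_avail_km = %s", num(ua@sdAvailKm)),
            sprintf("use.shift_km = %s", num(ua@shiftKm)),
            sprintf("use.shift_sd = %s",
                    if (is.na(ua@shiftSd)) "NA" else num(ua@shiftSd)),
            sprintf("use.frac_beyond_foray = %s",
                    num(ua@fracUsedBeyondForay)))
  if (!is.null(report$avoidance))
    ln <- c(ln,
            sprintf("avoidance.theta_m = %s", num(report$avoidance@thetaM)),
            sprintf("avoidance.s_m = %s", num(report$avoidance@sM)))
  if (!is.null(report$threat))
    ln <- c(ln, vapply(seq_len(nrow(report$threat)), function(i)
      sprintf("threat.%s = %s (%s)", report$threat$reserve_id[i],
              num(report$threat$dog_zone_habitat_km2[i]),
              as.character(report$threat$category[i])), character(1)))
  ln
}
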