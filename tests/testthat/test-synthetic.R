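# Synthetic landscape generator: determinism, structure, and the
# occurrence scenarios.

test_that("terrain is deterministic, spans the relief, and can be flat", {
  cfg <- landscapeConfig(seed = 61L, nRows = 60L, nCols = 60L)
  t1 <- generateTerrain(cfg)
  t2 <- generateTerrain(cfg)
  expect_identical(gridValues(t1), gridValues(t2))
  expect_false(identical(gridValues(generateTerrain(
    landscapeConfig(seed = 62L, nRows = 60L, nCols = 60L))),
    gridValues(t1)))
  expect_equal(diff(range(gridValues(t1))), cfg@reliefM)
  flat <- generateTerrain(landscapeConfig(seed = 61L, nRows = 10L,
                                          nCols = 10L, reliefM = 0))
  expect_equal(gridValues(flat), matrix(0, 10, 10))
})

test_that("terrain amplitude is stable across seeds", {
  for (seed in 1:10) {
    dem <- generateTerrain(landscapeConfig(seed = seed, nRows = 50L,
                                           nCols = 50L))
    expect_equal(diff(range(gridValues(dem))), 2000)
  }
})

test_that("residences concentrate at low elevations", {
  for (seed in c(63, 64, 65)) {
    cfg <- landscapeConfig(seed = seed)
    dem <- generateTerrain(cfg)
    res <- placeResidences(dem, cfg)
    expect_gt(nPoints(res), cfg@nVillages * cfg@housesPerVillage[1] - 1)
    inExt <- pointCoords(res)[, 1] >= 0 & pointCoords(res)[, 1] <= 20000 &
      pointCoords(res)[, 2] >= 0 & pointCoords(res)[, 2] <= 20000
    zAtRes <- extractValuesAtPoints(dem, pointSet(pointCoords(res)[inExt, ],
                                                  label = "residences"))
    expect_lt(mean(zAtRes), quantile(gridValues(dem), 0.4))
  }
  cfgNone <- landscapeConfig(seed = 63L, nVillages = 0L)
  expect_equal(nPoints(placeResidences(generateTerrain(cfgNone), cfgNone)), 0)
  cfg2 <- landscapeConfig(seed = 66L)
  dem2 <- generateTerrain(cfg2)
  expect_identical(pointCoords(placeResidences(dem2, cfg2)),
                   pointCoords(placeResidences(dem2, cfg2)))
})

test_that("habitat band and reserves behave at the extremes", {
  cfg <- landscapeConfig(seed = 67L, nRows = 50L, nCols = 50L)
  dem <- generateTerrain(cfg)
  all <- generateHabitatAndReserves(dem, landscapeConfig(
    seed = 67L, nRows = 50L, nCols = 50L, habitatBandM = c(-1, 2001)))
  expect_equal(maskAreaKm2(all$habitat), 25)
  expect_warning(none <- generateHabitatAndReserves(dem, landscapeConfig(
    seed = 67L, nRows = 50L, nCols = 50L, habitatBandM = c(5000, 6000))),
    "empty")
  expect_equal(maskAreaKm2(none$habitat), 0)
  expect_equal(nPolygons(none$reserves), 0)
})

test_that("every reserve polygon contains habitat cells", {
  for (seed in c(68, 69, 70)) {
    cfg <- landscapeConfig(seed = seed)
    dem <- generateTerrain(cfg)
    hr <- generateHabitatAndReserves(dem, cfg)
    expect_equal(nPolygons(hr$reserves), cfg@nReserves)
    for (i in seq_len(nPolygons(hr$reserves))) {
      one <- polygonSet(list(polygonRings(hr$reserves, i)), names = "x")
      inRes <- gridValues(rasterizePolygons(one, hr$habitat))
      h <- gridValues(hr$habitat)
      expect_gt(sum(inRes == 1 & !is.na(h) & h == 1), 0)
    }
  }
})

test_that("null-scenario occurrences mirror availability", {
  ls <- smallLandscape()
  occ <- simulateOccurrences(ls$surface, ls$habitat,
                             occurrenceConfig("null", n = 400L, seed = 71L))
  dOcc <- extractValuesAtPoints(distanceRaster(ls$surface), occ)
  avail <- sampleAvailable(ls$habitat, 2000, seed = 72L)
  dAv <- extractValuesAtPoints(distanceRaster(ls$surface), avail)
  se <- sd(dAv) * sqrt(1 / 400 + 1 / 2000)
  expect_lt(abs(mean(dOcc) - mean(dAv)), 3.5 * se)
})

test_that("many-dogs occurrences cluster beyond the foray distance", {
  fr <- sh <- numeric(0)
  for (seed in 73:77) {
    lc <- landscapeConfig(seed = seed)
    dem <- generateTerrain(lc)
    res <- placeResidences(dem, lc)
    hr <- generateHabitatAndReserves(dem, lc)
    surf <- surfacePathDistance(dem,
                                populatedMask(housingDensitySurface(res, dem)))
    occ <- simulateOccurrences(surf, hr$habitat,
                               occurrenceConfig("many_dogs", seed = seed))
    avail <- sampleAvailable(hr$habitat, 100, seed = seed + 1000L)
    s <- summarizeShift(extractValuesAtPoints(distanceRaster(surf), occ),
                        extractValuesAtPoints(distanceRaster(surf), avail))
    fr <- c(fr, s@fracUsedBeyondForay)
    sh <- c(sh, s@shiftSd)
  }
  # loose sanity bounds for this 5-seed smoke check; the full 20-seed
  # generative-signature thresholds are asserted in the acceptance suite
  expect_gte(median(fr), 0.7)
  expect_gte(median(sh), 1.2)
})

test_that("occurrence sampling is seed-reproducible and validated", {
  ls <- smallLandscape()
  o1 <- simulateOccurrences(ls$surface, ls$habitat,
                            occurrenceConfig("many_dogs", seed = 78L))
  o2 <- simulateOccurrences(ls$surface, ls$habitat,
                            occurrenceConfig("many_dogs", seed = 78L))
  expect_identical(pointCoords(o1), pointCoords(o2))
  empty <- gridRaster(matrix(0, nRows(ls$habitat), nCols(ls$habitat)),
                      origin(ls$habitat)["x"], origin(ls$habitat)["y"],
                      cellSize(ls$habitat), "mask")
  expect_error(simulateOccurrences(ls$surface, empty,
                                   occurrenceConfig("null", n = 5L)),
               "no habitat cells")
})
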