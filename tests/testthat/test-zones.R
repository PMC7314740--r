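# Zone extraction, effective habitat accounting, and the dog-free identity.

test_that("zone mask thresholds distances inclusively", {
  set.seed(31)
  dem <- randomRaster(12, 12, cellSize = 100, lo = 0, hi = 400)
  surf <- surfacePathDistance(dem, sourceAt(dem, cbind(c(2, 10), c(3, 11))))
  d <- gridValues(distanceRaster(surf))
  expect_equal(gridValues(zoneMask(surf, 0)),
               (d == 0) + 0) # exactly the source cells
  expect_equal(gridValues(zoneMask(surf, maxFiniteDistance(surf))),
               (d >= 0) + 0) # every finite cell
  dmed <- median(d)
  expect_equal(gridValues(zoneMask(surf, dmed)), (d <= dmed) + 0)
  expect_error(zoneMask(surf, -1), "'d'")
})

test_that("effective habitat matches a cell-by-cell filtered count", {
  set.seed(32)
  lc <- landscapeConfig(seed = 32L, nRows = 40L, nCols = 40L, nVillages = 4L,
                        housesPerVillage = c(10L, 20L))
  dem <- generateTerrain(lc)
  res <- placeResidences(dem, lc)
  pop <- populatedMask(housingDensitySurface(res, dem),
                       densityConfig(thresholdPerKm2 = 1))
  surf <- surfacePathDistance(dem, pop)
  hab <- generateHabitatAndReserves(dem, lc)$habitat
  cfg <- zoneConfig(humanImpactM = 500, forayM = 1500)
  rep <- effectiveHabitat(hab, surf, cfg)
  h <- gridValues(hab); d <- gridValues(distanceRaster(surf))
  nb <- ne1 <- ne2 <- 0
  for (r in 1:40) for (c in 1:40) {
    if (is.na(h[r, c]) || h[r, c] != 1) next
    nb <- nb + 1
    beyond <- function(thr) is.na(d[r, c]) || d[r, c] > thr
    if (beyond(500)) ne1 <- ne1 + 1
    if (beyond(1500)) ne2 <- ne2 + 1
  }
  cellKm2 <- 0.01
  expect_equal(rep@baselineKm2, nb * cellKm2)
  expect_equal(rep@effectiveIKm2, ne1 * cellKm2)
  expect_equal(rep@effectiveIIKm2, ne2 * cellKm2)
  expect_equal(rep@reductionIIPct, 100 * (nb - ne2) / nb)
})

test_that("reduction arithmetic reproduces the published accounting", {
  r <- effectiveHabitatReport(385.2, 380.3, 108.7)
  expect_equal(round(r@reductionIIPct), 72)
  r2 <- effectiveHabitatReport(271.2, 271.1, 63.9)
  expect_equal(round(r2@reductionIIPct), 76)
})

test_that("zero foray distance off sources leaves habitat untouched", {
  dem <- flatDem(6, 6, 100)
  surf <- surfacePathDistance(dem, sourceAt(dem, cbind(1, 1)))
  h <- matrix(1, 6, 6); h[1, 1] <- 0 # no habitat on the source cell
  hab <- gridRaster(h, 0, 600, 100, "mask")
  rep <- effectiveHabitat(hab, surf, zoneConfig(humanImpactM = 0, forayM = 0))
  expect_equal(rep@effectiveIIKm2, rep@baselineKm2)
  expect_equal(rep@reductionIIPct, 0)
})

test_that("unreachable habitat counts as dog-free with a warning", {
  z <- matrix(0, 5, 5); z[, 3] <- NA
  dem <- gridRaster(z, 0, 500, 100, "elevation_m")
  surf <- surfacePathDistance(dem, sourceAt(dem, cbind(3, 1)))
  hab <- gridRaster(matrix(1, 5, 5), 0, 500, 100, "mask")
  expect_warning(rep <- effectiveHabitat(hab, surf,
                                         zoneConfig(humanImpactM = 100,
                                                    forayM = 200)),
                 "unreachable")
  # the 10 right-side cells are unreachable, hence beyond both thresholds
  expect_gte(rep@effectiveIIKm2, 10 * 0.01)
})

test_that("dogFreePercent reproduces the range-wide tabulation", {
  expect_equal(dogFreePercent(25710, 10240),
               list(dogFreeKm2 = 15470, pct = 100 * 15470 / 25710))
  expect_equal(round(dogFreePercent(25710, 10240)$pct), 60)
  expect_equal(dogFreePercent(13720, 4060)$dogFreeKm2, 9660)
  expect_equal(round(dogFreePercent(13720, 4060)$pct), 70)
  expect_equal(dogFreePercent(123.4, 0), list(dogFreeKm2 = 123.4, pct = 100))
  expect_error(dogFreePercent(10, 11), "exceeds")
})

test_that("dog-zone and dog-free areas conserve the finite total", {
  set.seed(33)
  for (trial in 1:3) {
    dem <- randomRaster(15, 15, cellSize = 100, naFrac = 0.1, lo = 0, hi = 500)
    ok <- which(!is.na(gridValues(dem)))
    surf <- surfacePathDistance(dem, sourceAt(dem, ok[sample(length(ok), 2)]))
    d <- gridValues(distanceRaster(surf))
    totalKm2 <- sum(!is.na(d)) * 0.01
    for (thr in quantile(d, c(0.2, 0.5, 0.9), na.rm = TRUE)) {
      zone <- maskAreaKm2(zoneMask(surf, thr))
      free <- sum(!is.na(d) & d > thr) * 0.01
      expect_equal(zone + free, totalKm2)
    }
  }
})

test_that("zones nest and effective areas are monotone in the thresholds", {
  set.seed(34)
  dem <- randomRaster(12, 12, cellSize = 100, lo = 0, hi = 300)
  surf <- surfacePathDistance(dem, sourceAt(dem, cbind(6, 6)))
  m1 <- gridValues(zoneMask(surf, 300))
  m2 <- gridValues(zoneMask(surf, 800))
  expect_true(all(m2[m1 == 1] == 1)) # zone(d1) subset of zone(d2)
  hab <- randomMask(12, 12, cellSize = 100, pOne = 0.7)
  prev <- Inf
  for (foray in c(200, 500, 900, 1600)) {
    rep <- effectiveHabitat(hab, surf, zoneConfig(humanImpactM = 100,
                                                  forayM = foray))
    expect_lte(rep@effectiveIIKm2, prev)
    expect_lte(rep@effectiveIIKm2, rep@effectiveIKm2)
    expect_lte(rep@effectiveIKm2, rep@baselineKm2)
    prev <- rep@effectiveIIKm2
  }
})
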