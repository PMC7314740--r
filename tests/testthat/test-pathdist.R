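# Terrain-aware multi-source path distance against independent oracles.

test_that("flat-terrain steps cost the chamfer metric", {
  dem <- flatDem(5, 5, 30)
  surf <- surfacePathDistance(dem, sourceAt(dem, cbind(3, 3)))
  d <- gridValues(distanceRaster(surf))
  expect_equal(d[3, 3], 0)
  expect_equal(d[3, 4], 30)
  expect_equal(d[2, 2], 30 * sqrt(2))
})

test_that("a single step over relief costs the slope length", {
  # elevations 0 and 40 m across a 30 m cell: 3-4-5 triangle
  dem <- gridRaster(matrix(c(0, 40), 1, 2), 0, 30, 30, "elevation_m")
  surf <- surfacePathDistance(dem, sourceAt(dem, cbind(1, 1)))
  expect_equal(gridValues(distanceRaster(surf))[1, 2], 50)
})

test_that("distances match a relaxation oracle on rugged nodata terrain", {
  set.seed(21)
  for (trial in 1:5) {
    dem <- randomRaster(6, 6, cellSize = 30, naFrac = 0.15, lo = 0, hi = 120)
    ok <- which(!is.na(gridValues(dem)))
    src <- sourceAt(dem, ok[sample(length(ok), 2)])
    got <- gridValues(distanceRaster(surfacePathDistance(dem, src)))
    expect_equal(got, bruteForcePathDistance(dem, src), tolerance = 1e-9)
  }
})

test_that("flat single-source distances equal the chamfer closed form", {
  dem <- flatDem(12, 17, 100)
  surf <- surfacePathDistance(dem, sourceAt(dem, cbind(4, 9)))
  d <- gridValues(distanceRaster(surf))
  for (r in seq_len(12)) for (c in seq_len(17)) {
    dr <- abs(r - 4); dc <- abs(c - 9)
    expect_equal(d[r, c], 100 * (sqrt(2) * min(dr, dc) + abs(dr - dc)),
                 tolerance = 1e-12)
  }
})

test_that("nodata barriers force paths around and isolate enclaves", {
  # wall of nodata with no gap: right side unreachable
  z <- matrix(0, 5, 5); z[, 3] <- NA
  dem <- gridRaster(z, 0, 500, 100, "elevation_m")
  surf <- surfacePathDistance(dem, sourceAt(dem, cbind(3, 1)))
  d <- gridValues(distanceRaster(surf))
  expect_true(all(is.na(d[, 3:5])))
  expect_true(all(!is.na(d[, 1:2])))
  # gap in the wall: paths route through it
  z2 <- z; z2[5, 3] <- 0
  dem2 <- gridRaster(z2, 0, 500, 100, "elevation_m")
  d2 <- gridValues(distanceRaster(surfacePathDistance(dem2,
                                                      sourceAt(dem2, cbind(3, 1)))))
  expect_false(anyNA(d2[, 4:5]))
  expect_equal(d2[5, 3], bruteForcePathDistance(dem2,
                                                sourceAt(dem2, cbind(3, 1)))[5, 3],
               tolerance = 1e-9)
})

test_that("triangle inequality holds between adjacent cells", {
  set.seed(22)
  dem <- randomRaster(10, 10, cellSize = 50, lo = 0, hi = 300)
  surf <- surfacePathDistance(dem, sourceAt(dem, cbind(c(2, 9), c(2, 7))))
  d <- gridValues(distanceRaster(surf))
  z <- gridValues(dem)
  for (r in 1:10) for (c in 1:10) for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > 10 || c2 < 1 || c2 > 10) next
    h <- if (dr != 0 && dc != 0) 50 * sqrt(2) else 50
    step <- sqrt(h^2 + (z[r, c] - z[r2, c2])^2)
    expect_lte(abs(d[r, c] - d[r2, c2]), step + 1e-9)
  }
})

test_that("scaling relief up never shortens distances", {
  set.seed(23)
  dem <- randomRaster(8, 8, cellSize = 50, lo = 0, hi = 200)
  src <- sourceAt(dem, cbind(1, 1))
  d1 <- gridValues(distanceRaster(surfacePathDistance(dem, src)))
  dem2 <- gridRaster(gridValues(dem) * 3, 0, 8 * 50, 50, "elevation_m")
  d2 <- gridValues(distanceRaster(surfacePathDistance(dem2, src)))
  expect_true(all(d2 >= d1 - 1e-9))
})

test_that("adding source cells never increases any distance", {
  set.seed(24)
  dem <- randomRaster(8, 8, cellSize = 50, lo = 0, hi = 200)
  d1 <- gridValues(distanceRaster(surfacePathDistance(dem,
                                                      sourceAt(dem, cbind(1, 1)))))
  d2 <- gridValues(distanceRaster(surfacePathDistance(dem,
                                                      sourceAt(dem, cbind(c(1, 5), c(1, 6))))))
  expect_true(all(d2 <= d1 + 1e-9))
})

test_that("maxFiniteDistance scans finite cells only", {
  dem <- flatDem(1, 3, 1000)
  all_src <- gridRaster(matrix(1, 1, 3), 0, 1000, 1000, "mask")
  expect_equal(maxFiniteDistance(surfacePathDistance(dem, all_src)), 0)
  end_src <- sourceAt(dem, cbind(1, 1))
  expect_equal(maxFiniteDistance(surfacePathDistance(dem, end_src)), 2000)
  set.seed(25)
  dem2 <- randomRaster(7, 7, cellSize = 40, naFrac = 0.2)
  ok <- which(!is.na(gridValues(dem2)))
  surf <- surfacePathDistance(dem2, sourceAt(dem2, ok[1]))
  d <- gridValues(distanceRaster(surf))
  expect_equal(maxFiniteDistance(surf), max(d[is.finite(d)]))
})

test_that("degenerate inputs are rejected with clear errors", {
  dem <- flatDem(4, 4, 30)
  expect_error(surfacePathDistance(dem, sourceAt(dem, integer())),
               "no source cells")
  z <- matrix(NA_real_, 4, 4); z[1, 1] <- 0
  demHole <- gridRaster(z, 0, 120, 30, "elevation_m")
  expect_error(surfacePathDistance(demHole, sourceAt(demHole, cbind(4, 4))),
               "source")
})
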