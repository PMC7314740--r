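# Core raster/vector data model: rasterization, area accounting, value
# extraction, validity, and plain-text I/O round trips.

test_that("GridRaster validity enforces the data-model invariants", {
  expect_error(gridRaster(matrix(0, 2, 2), cellSize = -1), "cellSize")
  expect_error(gridRaster(matrix(Inf, 2, 2), cellSize = 10), "finite")
  expect_error(gridRaster(matrix(2, 2, 2), cellSize = 10, kind = "mask"),
               "mask")
  expect_error(gridRaster(matrix(-5, 2, 2), cellSize = 10,
                          kind = "distance_m"), "negative")
  m <- gridRaster(matrix(c(0, 1, NA, 1), 2, 2), cellSize = 10, kind = "mask")
  expect_s4_class(m, "GridRaster")
  expect_identical(rasterKind(m), "mask")
})

test_that("rasterizePolygons covers trivial full and empty cases", {
  tmpl <- gridRaster(matrix(0, 10, 10), 0, 1000, 100)
  full <- rbind(c(-10, -10), c(1010, -10), c(1010, 1010), c(-10, 1010))
  expect_equal(gridValues(rasterizePolygons(polygonSet(list(full)), tmpl)),
               matrix(1, 10, 10))
  expect_equal(gridValues(rasterizePolygons(polygonSet(), tmpl)),
               matrix(0, 10, 10))
})

test_that("rasterizePolygons marks exactly the covered cell centers", {
  # 10x10 grid, cells 1 m: a unit square covering the centers of a 2x2
  # block; expected mask computed by brute-force point-in-polygon over all
  # 100 centers
  tmpl <- gridRaster(matrix(0, 10, 10), 0, 10, 1)
  sq <- rbind(c(2.4, 2.4), c(4.4, 2.4), c(4.4, 4.4), c(2.4, 4.4))
  m <- rasterizePolygons(polygonSet(list(sq)), tmpl)
  expected <- matrix(0, 10, 10)
  for (r in 1:10) for (c in 1:10) {
    cx <- c - 0.5; cy <- 10 - r + 0.5
    if (cx >= 2.4 && cx <= 4.4 && cy >= 2.4 && cy <= 4.4)
      expected[r, c] <- 1
  }
  expect_equal(gridValues(m), expected)
  expect_equal(sum(gridValues(m)), 4)
})

test_that("rasterizePolygons respects holes via the even-odd rule", {
  tmpl <- gridRaster(matrix(0, 10, 10), 0, 10, 1)
  outer <- rbind(c(0.9, 0.9), c(9.1, 0.9), c(9.1, 9.1), c(0.9, 9.1))
  hole <- rbind(c(3.9, 3.9), c(6.1, 3.9), c(6.1, 6.1), c(3.9, 6.1))
  m <- rasterizePolygons(polygonSet(list(list(outer, hole))), tmpl)
  v <- gridValues(m)
  expect_equal(v[2, 2], 1) # center (1.5, 8.5): inside outer only
  expect_equal(v[6, 5], 0) # center (4.5, 4.5): inside the hole
  expect_equal(sum(v), 8 * 8 - 2 * 2)
})

test_that("mask area matches an independent cell count", {
  m <- gridRaster(matrix(c(rep(1, 10), rep(0, 90)), 10, 10), 0, 1000, 100,
                  kind = "mask")
  expect_equal(maskAreaKm2(m), 0.1)
  expect_equal(maskAreaKm2(gridRaster(matrix(0, 5, 5), 0, 500, 100, "mask")),
               0)
  set.seed(42)
  rm50 <- randomMask(50, 50, cellSize = 70)
  count <- 0
  v <- gridValues(rm50)
  for (r in 1:50) for (c in 1:50) if (!is.na(v[r, c]) && v[r, c] == 1)
    count <- count + 1
  expect_equal(maskAreaKm2(rm50), count * 70^2 / 1e6)
  expect_error(maskAreaKm2(randomRaster(3, 3)), "kind 'mask'")
})

test_that("rasterized area converges to polygon area as cells shrink", {
  # 3 km x 3 km square offset awkwardly inside a 10 km domain
  sq <- rbind(c(2130, 1870), c(5130, 1870), c(5130, 4870), c(2130, 4870))
  ps <- polygonSet(list(sq))
  err <- vapply(c(100, 50, 25), function(cs) {
    n <- 10000 / cs
    tmpl <- gridRaster(matrix(0, n, n), 0, 10000, cs)
    abs(maskAreaKm2(rasterizePolygons(ps, tmpl)) - 9)
  }, numeric(1))
  expect_true(all(diff(err) <= 0))
})

test_that("value extraction uses the nearest cell center and keeps order", {
  r <- gridRaster(matrix(1:20, 4, 5), 0, 400, 100)
  # exactly at the center of cell (2, 3)
  expect_equal(extractValuesAtPoints(r, pointSet(250, 250)),
               gridValues(r)[2, 3])
  expect_equal(extractValuesAtPoints(r, pointSet(label = "empty")),
               numeric())
  set.seed(7)
  rr <- randomRaster(8, 9, cellSize = 50, naFrac = 0.1)
  pts <- pointSet(runif(20, 0, 9 * 50), runif(20, 0, 8 * 50))
  got <- extractValuesAtPoints(rr, pts)
  xs <- origin(rr)["x"] + (seq_len(nCols(rr)) - 0.5) * 50
  ys <- origin(rr)["y"] - (seq_len(nRows(rr)) - 0.5) * 50
  exp <- vapply(seq_len(20), function(i) {
    p <- pointCoords(pts)[i, ]
    best <- c(Inf, NA, NA)
    for (r2 in seq_len(nRows(rr))) for (c2 in seq_len(nCols(rr))) {
      d2 <- (xs[c2] - p[1])^2 + (ys[r2] - p[2])^2
      if (d2 < best[1]) best <- c(d2, r2, c2)
    }
    gridValues(rr)[best[2], best[3]]
  }, numeric(1))
  expect_identical(got, exp)
  # idempotent re-query, permutation equivariance
  expect_identical(extractValuesAtPoints(rr, pts), got)
  perm <- sample(20)
  expect_identical(extractValuesAtPoints(rr, pointSet(pointCoords(pts)[perm, ])),
                   got[perm])
})

test_that("points outside the raster extent are reported by index", {
  r <- gridRaster(matrix(0, 4, 4), 0, 400, 100)
  expect_error(extractValuesAtPoints(r, pointSet(c(50, 450, 100), c(50, 50, -3))),
               "index: 2, 3")
})

test_that("rasters survive an ASCII grid round trip exactly", {
  set.seed(3)
  r <- randomRaster(7, 5, cellSize = 33.25, naFrac = 0.15,
                    lo = -1234.5678, hi = 9876.5432)
  p <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(r, p)
  r2 <- readAsciiGrid(p, kind = "elevation_m")
  expect_equal(gridValues(r2), gridValues(r), tolerance = 0)
  expect_identical(origin(r2), origin(r))
  expect_identical(cellSize(r2), cellSize(r))
})

test_that("point sets survive CSV and GeoJSON round trips", {
  set.seed(4)
  pts <- pointSet(runif(13, -1e5, 1e5), runif(13, -1e5, 1e5), "residences")
  csv <- withr::local_tempfile(fileext = ".csv")
  writePointsCsv(pts, csv)
  back <- readPointsCsv(csv, label = "residences")
  expect_equal(pointCoords(back), pointCoords(pts), tolerance = 1e-12)
  gj <- withr::local_tempfile(fileext = ".geojson")
  writeGeoJSON(pts, gj)
  back2 <- readGeoJSONPoints(gj)
  expect_equal(pointCoords(back2), pointCoords(pts), tolerance = 0,
               ignore_attr = TRUE)
  expect_identical(pointLabel(back2), "residences")
})

test_that("polygon sets survive a GeoJSON round trip", {
  sq <- rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000))
  tri <- rbind(c(2000, 0), c(3000, 0), c(2500, 900))
  ps <- polygonSet(list(sq, tri), names = c("a", "b"))
  gj <- withr::local_tempfile(fileext = ".geojson")
  writeGeoJSON(ps, gj)
  back <- readGeoJSONPolygons(gj)
  expect_identical(polygonNames(back), c("a", "b"))
  expect_equal(polygonRings(back, 1)[[1]], polygonRings(ps, 1)[[1]],
               ignore_attr = TRUE)
  tmpl <- gridRaster(matrix(0, 20, 40), 0, 2000, 100)
  expect_equal(gridValues(rasterizePolygons(back, tmpl)),
               gridValues(rasterizePolygons(ps, tmpl)))
})

test_that("combining misaligned rasters is rejected", {
  dem <- flatDem(5, 5, 30)
  src <- gridRaster(matrix(1, 5, 5), 1, 150, 30, "mask")
  expect_error(surfacePathDistance(dem, src), "georeferencing")
})
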