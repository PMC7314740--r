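# Shared fixture builders and independent oracles. Oracles deliberately use
# naive algorithms (double loops, exhaustive enumeration, igraph) so they
# stay independent of the implementation paths they check.

# random raster with optional nodata holes
randomRaster <- function(nr, nc, cellSize = 100, kind = "elevation_m",
                         naFrac = 0, lo = 0, hi = 100) {
  v <- matrix(runif(nr * nc, lo, hi), nr, nc)
  if (naFrac > 0) v[sample.int(nr * nc, ceiling(naFrac * nr * nc))] <- NA
  gridRaster(v, 0, nr * cellSize, cellSize, kind = kind)
}

randomMask <- function(nr, nc, cellSize = 100, pOne = 0.5) {
  v <- matrix(rbinom(nr * nc, 1, pOne), nr, nc)
  gridRaster(v, 0, nr * cellSize, cellSize, kind = "mask")
}

flatDem <- function(nr, nc, cellSize = 30, z = 0) {
  gridRaster(matrix(z, nr, nc), 0, nr * cellSize, cellSize, "elevation_m")
}

sourceAt <- function(dem, cells) {
  v <- matrix(0, nRows(dem), nCols(dem))
  v[cells] <- 1
  gridRaster(v, origin(dem)["x"], origin(dem)["y"], cellSize(dem), "mask")
}

# independent shortest-path oracle: explicit 8-neighbor edge list + igraph
# Dijkstra; returns the matrix of min distances from any source cell
igraphPathDistance <- function(dem, sources) {
  z <- gridValues(dem)
  nr <- nrow(z); nc <- ncol(z); cs <- cellSize(dem)
  id <- function(r, c) (c - 1L) * nr + r
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(z[r, c])) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(z[r2, c2])) next
      if (id(r2, c2) <= id(r, c)) next # one record per undirected edge
      h <- if (dr != 0 && dc != 0) cs * sqrt(2) else cs
      from <- c(from, id(r, c)); to <- c(to, id(r2, c2))
      w <- c(w, sqrt(h^2 + (z[r, c] - z[r2, c2])^2))
    }
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = w), directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(nr * nc))))
  srcCells <- which(gridValues(sources) == 1 & !is.na(z))
  dm <- igraph::distances(g, v = as.character(srcCells),
                          weights = igraph::E(g)$weight)
  d <- matrix(suppressWarnings(apply(dm, 2, min))[
    match(as.character(seq_len(nr * nc)), colnames(dm))], nr, nc)
  d[is.infinite(d)] <- NA
  d[is.na(z)] <- NA
  d
}

# simpler, robust oracle: Bellman-Ford style relaxation in plain R
bruteForcePathDistance <- function(dem, sources) {
  z <- gridValues(dem)
  nr <- nrow(z); nc <- ncol(z); cs <- cellSize(dem)
  d <- matrix(Inf, nr, nc)
  d[gridValues(sources) == 1 & !is.na(z)] <- 0
  d[is.na(z)] <- NA
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (is.na(z[r, c])) next
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || is.na(z[r2, c2])) next
        h <- if (dr != 0 && dc != 0) cs * sqrt(2) else cs
        cand <- d[r2, c2] + sqrt(h^2 + (z[r, c] - z[r2, c2])^2)
        if (is.finite(cand) && cand < d[r, c] - 1e-12) {
          d[r, c] <- cand; changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d[is.infinite(d)] <- NA
  d
}

# exhaustive Jenks oracle: enumerate all contiguous k-partitions
bruteForceJenks <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  ssd <- function(x) if (length(x) <= 1) 0 else sum((x - mean(x))^2)
  best <- Inf; bestBounds <- NULL
  combs <- utils::combn(n - 1, k - 1)
  if (k == 1) return(list(ssd = ssd(v), bounds = integer(0)))
  for (j in seq_len(ncol(combs))) {
    b <- combs[, j]
    edges <- c(0, b, n)
    tot <- sum(vapply(seq_len(k), function(i)
      ssd(v[(edges[i] + 1):edges[i + 1]]), numeric(1)))
    if (tot < best - 1e-12) { best <- tot; bestBounds <- b }
  }
  list(ssd = best, bounds = bestBounds)
}

# small landscape + surface used by several suites (cached per session)
smallLandscape <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lc <- landscapeConfig(seed = 11L, nRows = 100L, nCols = 100L,
                            nVillages = 8L)
      dem <- generateTerrain(lc)
      res <- placeResidences(dem, lc)
      hr <- generateHabitatAndReserves(dem, lc)
      pop <- populatedMask(housingDensitySurface(res, dem))
      surf <- surfacePathDistance(dem, pop)
      cache <<- list(cfg = lc, dem = dem, residences = res,
                     habitat = hr$habitat, reserves = hr$reserves,
                     surface = surf)
    }
    cache
  }
})
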