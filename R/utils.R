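## Internal helpers shared across modules.

# Signed area of a ring (shoelace); positive for counter-clockwise rings.
.ringArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

# Do two rasters share origin, cell size and shape exactly?
.sameGeoref <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    isTRUE(all.equal(a@originX, b@originX, tolerance = 0)) &&
    isTRUE(all.equal(a@originY, b@originY, tolerance = 0)) &&
    isTRUE(all.equal(a@cellSize, b@cellSize, tolerance = 0))
}

.stopIfMisaligned <- function(a, b, what = "rasters") {
  if (!.sameGeoref(a, b))
    stop(what, " must share identical georeferencing (origin, cell size, ",
         "shape); resample explicitly before combining", call. = FALSE)
  invisible(TRUE)
}

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# x/y coordinates of all cell centers, as vectors of length nCols / nRows.
.centerXs <- function(r) r@originX + (seq_len(ncol(r@values)) - 0.5) * r@cellSize
.centerYs <- function(r) r@originY - (seq_len(nrow(r@values)) - 0.5) * r@cellSize

.checkCount <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  as.integer(x)
}

.checkScalar <- function(x, name, min = -Inf, strict = FALSE) {
  if (length(x) != 1L || !is.finite(x) ||
      (strict && x <= min) || (!strict && x < min))
    stop("'", name, "' must be a single finite number ",
         if (strict) "> " else ">= ", min, call. = FALSE)
  as.numeric(x)
}
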