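## Use versus availability: sample random available locations from habitat,
## compare the path-distance distribution of occurrences against them, and
## optionally fit a logistic avoidance model to formalize the shift.

#' Sample random available locations from a habitat mask
#'
#' Draws points uniformly over the union of habitat cells: a cell is chosen
#' uniformly among the 1 cells (with replacement) and the position is
#' uniform within that cell. Reproducible for a fixed seed; the caller's
#' RNG state is left untouched.
#'
#' @param habitat a [GridRaster-class] mask with at least one 1 cell when
#'   `n > 0`.
#' @param n number of points.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a [PointSet-class] labelled `"available"`.
#' @export
sampleAvailable <- function(habitat, n, seed = NULL) {
  stopifnot(is(habitat, "GridRaster"))
  if (!identical(habitat@kind, "mask"))
    stop("'habitat' must be a raster of kind 'mask'", call. = FALSE)
  n <- .checkCount(n, "n")
  if (n == 0L) return(pointSet(label = "available"))
  ones <- which(!is.na(habitat@values) & habitat@values == 1)
  if (!length(ones))
    stop("habitat mask is empty: cannot sample available locations",
         call. = FALSE)
  .withSeed(seed, {
    cells <- ones[sample.int(length(ones), n, replace = TRUE)]
    r <- ((cells - 1L) %% nRows(habitat)) + 1L
    c <- ((cells - 1L) %/% nRows(habitat)) + 1L
    cs <- habitat@cellSize
    x <- habitat@originX + (c - 1L + runif(n)) * cs
    y <- habitat@originY - (r - 1L + runif(n)) * cs
    pointSet(x, y, label = "available")
  })
}

#' Summarize the shift of used locations away from populated areas
#'
#' Compares the path-distance distribution of occurrence ("used") locations
#' against available locations. The shift is the difference of means, and
#' `shiftSd` expresses it in availability standard deviations (sample SD,
#' n - 1 denominator); a shift of about two availability SDs is the
#' signature of strong avoidance. Also reports the fraction of used
#' distances strictly beyond the foray threshold.
#'
#' @param usedD numeric vector of used path distances, meters.
#' @param availD numeric vector of available path distances, meters.
#' @param cfg a [ZoneConfig-class] supplying the foray distance.
#' @return a [UseAvailabilityResult-class]; distances reported in km.
#' @examples
#' res <- summarizeShift(rep(12400, 20), rep(c(5000, 5200), 10), zoneConfig())
#' res@shiftKm
#' @export
summarizeShift <- function(usedD, availD, cfg = zoneConfig()) {
  stopifnot(is(cfg, "ZoneConfig"))
  if (!length(usedD) || !length(availD))
    stop("both distance lists must be non-empty", call. = FALSE)
  if (anyNA(usedD) || anyNA(availD))
    stop("distance lists may not contain NA", call. = FALSE)
  sdAvail <- sd(availD)
  shift <- mean(usedD) - mean(availD)
  shiftSd <- if (sdAvail > 0) shift / sdAvail else {
    warning("availability distances have zero variance; shiftSd undefined",
            call. = FALSE)
    NA_real_
  }
  new("UseAvailabilityResult",
      nUsed = length(usedD), nAvailable = length(availD),
      meanUsedKm = mean(usedD) / 1000, meanAvailKm = mean(availD) / 1000,
      sdAvailKm = sdAvail / 1000, shiftKm = shift / 1000,
      shiftSd = shiftSd,
      fracUsedBeyondForay = mean(usedD > cfg@forayM))
}

# Log-likelihood of the logistic avoidance model given binned availability.
# a: per-bin availability mass (pseudocounted); mids: bin midpoints;
# usedBin: bin index per used distance.
.avoidLogLik <- function(theta, s, usedD, usedBin, a, mids) {
  w <- plogis((usedD - theta) / s)
  wb <- plogis((mids - theta) / s)
  denom <- sum(wb * a)
  if (denom <= 0 || any(w <= 0)) return(-Inf)
  sum(log(w * a[usedBin])) - length(usedD) * log(denom)
}

#' Fit a logistic avoidance model to used and available distances
#'
#' Models the relative probability of use at path distance d as
#' `w(d) = 1 / (1 + exp(-(d - theta) / s))` times the availability density,
#' the latter approximated by a histogram over `nBins` equal-width bins
#' spanning the pooled distance range (bins receive a 0.5-count pseudocount
#' so empty availability bins do not produce infinite log-likelihoods). The
#' likelihood is maximized over a fixed grid of (theta, s) followed by a
#' local Nelder-Mead refinement, so the fit is deterministic given the
#' inputs.
#'
#' This parametric summary is an extension beyond the visual use-vs-
#' availability comparison; it is reported only when requested.
#'
#' @param usedD used path distances, meters (>= 10 values).
#' @param availD available path distances, meters (>= 10 values).
#' @param nBins number of availability bins (>= 4).
#' @return an [AvoidanceModel-class].
#' @export
fitAvoidance <- function(usedD, availD, nBins = 20L) {
  nBins <- .checkCount(nBins, "nBins", min = 4L)
  if (length(usedD) < 10L || length(availD) < 10L)
    stop("need at least 10 used and 10 available distances", call. = FALSE)
  pool <- c(usedD, availD)
  lo <- min(pool); hi <- max(pool)
  if (hi <= lo)
    stop("avoidance fit failed: all distances are identical (degenerate)",
         call. = FALSE)
  brks <- seq(lo, hi, length.out = nBins + 1L)
  mids <- (brks[-1] + brks[-length(brks)]) / 2
  binOf <- function(d) pmin(nBins, pmax(1L, findInterval(d, brks,
                                                         rightmost.closed = TRUE)))
  a <- tabulate(binOf(availD), nBins) + 0.5
  usedBin <- binOf(usedD)

  span <- hi - lo
  thetaGrid <- seq(lo - 0.25 * span, hi + 0.25 * span, length.out = 41L)
  sGrid <- exp(seq(log(span / 200), log(2 * span), length.out = 25L))
  best <- c(-Inf, NA, NA)
  for (th in thetaGrid) for (s in sGrid) {
    ll <- .avoidLogLik(th, s, usedD, usedBin, a, mids)
    if (ll > best[1]) best <- c(ll, th, s)
  }
  if (!is.finite(best[1]))
    stop("avoidance fit failed: likelihood degenerate on the whole grid",
         call. = FALSE)
  fit <- optim(c(best[2], log(best[3])), function(p)
    -.avoidLogLik(p[1], exp(p[2]), usedD, usedBin, a, mids),
    method = "Nelder-Mead",
    control = list(maxit = 500L, reltol = 1e-10))
  new("AvoidanceModel", thetaM = fit$par[1], sM = exp(fit$par[2]),
      logLik = -fit$value)
}

#' Free-roaming dog density
#'
#' @param nFreeRoaming number of free-roaming dogs.
#' @param areaKm2 reference area, km^2 (> 0).
#' @return dogs per km^2 (full precision; round to 2 decimals for
#'   reporting).
#' @examples
#' round(dogDensity(212, 479), 2)  # 0.44
#' @export
dogDensity <- function(nFreeRoaming, areaKm2) {
  nFreeRoaming <- .checkCount(nFreeRoaming, "nFreeRoaming")
  areaKm2 <- .checkScalar(areaKm2, "areaKm2", min = 0, strict = TRUE)
  nFreeRoaming / areaKm2
}
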