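#' Savitzky-Golay smoothing of a melt curve
#'
#' Local-polynomial (Savitzky-Golay) smoothing of the fluorescence trace on
#' its own grid.  Any polynomial of degree <= `poly_order` is reproduced
#' exactly (including at the edges, where the filter refits the first and
#' last half-windows), so smoothing never biases a locally polynomial melt
#' signal; it only attenuates high-frequency noise.
#'
#' Defaults (11 points = 2.2 degC at the 0.2 degC ramp, cubic) preserve
#' melting transitions of width >= 0.8 degC while roughly halving the
#' point-wise noise standard deviation.
#'
#' @param curve A [melt_curve].
#' @param window_points Odd filter length, >= `poly_order + 2`, <= curve
#'   length.
#' @param poly_order Polynomial order of the local fit.
#' @return A smoothed [melt_curve] on the same grid.
#' @export
smooth_curve <- function(curve, window_points = 11L, poly_order = 3L) {
  stopifnot(inherits(curve, "melt_curve"))
  window_points <- as.integer(window_points)
  poly_order <- as.integer(poly_order)
  if (window_points %% 2L == 0L)
    stop("window_points must be odd")
  if (window_points < poly_order + 2L)
    stop("window_points must be >= poly_order + 2")
  if (window_points > length(curve$temperatures))
    stop("window_points exceeds curve length")
  sm <- signal::sgolayfilt(curve$fluorescence, p = poly_order,
                           n = window_points)
  melt_curve(curve$well_id, curve$sample_id, curve$temperatures, sm)
}

#' Negative derivative (-dF/dT) of a melt curve
#'
#' The derivative plot: melting transitions appear as peaks whose position is
#' the melting temperature (Tm) and whose height tracks the amount of
#' dissociating product.  Central differences on the interior grid, one-sided
#' differences at the two edges; output length equals input length.  Exact
#' for quadratics on a uniform grid.
#'
#' @param curve A [melt_curve] (usually smoothed first).
#' @return An object of class `derivative_curve` with fields `sample_id`,
#'   `well_id`, `temperatures` and `neg_dfdt` (a.u. per degC).
#' @export
negative_derivative <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  tt <- curve$temperatures
  ff <- curve$fluorescence
  n <- length(tt)
  d <- numeric(n)
  d[1L] <- (ff[2L] - ff[1L]) / (tt[2L] - tt[1L])
  d[n] <- (ff[n] - ff[n - 1L]) / (tt[n] - tt[n - 1L])
  i <- 2:(n - 1L)
  d[i] <- (ff[i + 1L] - ff[i - 1L]) / (tt[i + 1L] - tt[i - 1L])
  structure(
    list(sample_id = curve$sample_id, well_id = curve$well_id,
         temperatures = tt, neg_dfdt = -d),
    class = "derivative_curve")
}

#' @export
print.derivative_curve <- function(x, ...) {
  cat(sprintf("<derivative_curve> sample %s: %d points, max -dF/dT %.4g at %.1f degC\n",
              x$sample_id, length(x$temperatures),
              max(x$neg_dfdt), x$temperatures[which.max(x$neg_dfdt)]))
  invisible(x)
}

#' Difference curve against a wild-type reference
#'
#' Point-wise fluorescence difference between a sample and a reference melt
#' curve on a shared grid.  The convention here is `sample - reference`, so a
#' sample with more melting product than the wild-type control shows a
#' positive excursion; set `invert = TRUE` for the opposite
#' (`reference - sample`) orientation.
#'
#' @param sample,reference [melt_curve] objects on the same temperature grid
#'   (within 1e-6 degC).
#' @param invert If `TRUE`, return `reference - sample`.
#' @return A [melt_curve] holding the difference trace (sample's IDs kept).
#' @export
difference_curve <- function(sample, reference, invert = FALSE) {
  stopifnot(inherits(sample, "melt_curve"), inherits(reference, "melt_curve"))
  if (!same_grid(sample$temperatures, reference$temperatures))
    stop("sample and reference curves are not on a shared temperature grid")
  d <- sample$fluorescence - reference$fluorescence
  if (invert) d <- -d
  melt_curve(sample$well_id, sample$sample_id, sample$temperatures, d)
}

#' Detect melting peaks in a derivative curve
#'
#' Local maxima of -dF/dT inside a temperature window, filtered by
#' topographic prominence relative to the curve's global maximum.  Prominence
#' of a peak is its height minus the higher of the two lowest points
#' separating it from higher terrain (or from the window edge).  Peaks are
#' returned sorted by height, descending; ties between equal-height peaks are
#' broken in favour of the lower temperature.
#'
#' @param dcurve A `derivative_curve`.
#' @param window Length-2 numeric, degC limits of the search window (must
#'   overlap the grid).
#' @param min_prominence_frac Minimum prominence as a fraction of the global
#'   maximum of `neg_dfdt` (default 0.1, suppressing noise ripples).
#' @return A data.frame with one row per peak: `tm` (degC), `height`
#'   (a.u./degC, > 0), `prominence` (a.u./degC).  Zero rows if no peak
#'   qualifies.
#' @export
detect_peaks <- function(dcurve, window, min_prominence_frac = 0.1) {
  stopifnot(inherits(dcurve, "derivative_curve"),
            is.numeric(window), length(window) == 2L)
  tt <- dcurve$temperatures
  yy <- dcurve$neg_dfdt
  sel <- which(tt >= min(window) & tt <= max(window))
  if (length(sel) < 3L)
    stop("peak-detection window contains fewer than 3 grid points")
  y <- yy[sel]
  t_w <- tt[sel]
  n <- length(y)
  # interior local maxima (plateaus: take the first point of the plateau)
  is_max <- logical(n)
  for (i in 2:(n - 1L)) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) is_max[i] <- TRUE
    }
  }
  idx <- which(is_max)
  if (!length(idx))
    return(data.frame(tm = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(idx, function(i) {
    h <- y[i]
    lmin <- h; j <- i
    while (j > 1L && y[j - 1L] <= h) { j <- j - 1L; lmin <- min(lmin, y[j]) }
    rmin <- h; j <- i
    while (j < n && y[j + 1L] <= h) { j <- j + 1L; rmin <- min(rmin, y[j]) }
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- y[idx] > 0 & prom >= min_prominence_frac * max(yy)
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx))
    return(data.frame(tm = numeric(0), height = numeric(0),
                      prominence = numeric(0)))
  out <- data.frame(tm = t_w[idx], height = y[idx], prominence = prom)
  out[order(-out$height, out$tm), , drop = FALSE]
}
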