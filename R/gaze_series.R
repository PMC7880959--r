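#' Construct a gaze coordinate series
#'
#' A `gaze_series` holds paired horizontal/vertical gaze coordinate traces in
#' screen pixels, sampled at a fixed rate, together with the pixel-to-degree
#' conversion factor needed to express eye velocities in degrees of visual
#' angle per second.  Missing samples (signal loss, e.g. during blinks) are
#' encoded as `NA` identically in both coordinates.
#'
#' @param x,y Numeric vectors of equal length (>= 2): per-sample horizontal and
#'   vertical gaze coordinates in pixels.  Non-finite values mark missing
#'   samples.
#' @param sampling_rate Sampling rate in Hz (scalar > 0).
#' @param px2deg Visual degrees spanned by a single (square) pixel at the
#'   recording's viewing distance (scalar > 0).
#'
#' @return An object of class `gaze_series` with elements `x`, `y`,
#'   `sampling_rate`, `px2deg`.
#' @examples
#' gs <- gaze_series(x = c(0, 1, 2, 3), y = c(0, 0, 0, 0),
#'                   sampling_rate = 1000, px2deg = 0.01)
#' @export
gaze_series <- function(x, y, sampling_rate, px2deg) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have identical length")
  if (length(x) < 2L)
    stop("a gaze series needs at least 2 samples")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number (Hz)")
  if (!is.numeric(px2deg) || length(px2deg) != 1L ||
      !is.finite(px2deg) || px2deg <= 0)
    stop("px2deg must be a single positive number (deg/px)")
  # missing markers must agree between axes; signal loss is normalized to
  # NaN (dilate_signal_loss() later adds plain-NA margins around it, which
  # count as missing everywhere but do not re-qualify as loss windows)
  miss <- !is.finite(x) | !is.finite(y)
  x[miss] <- NaN
  y[miss] <- NaN
  structure(
    list(x = x, y = y,
         sampling_rate = as.numeric(sampling_rate),
         px2deg = as.numeric(px2deg)),
    class = "gaze_series")
}

#' @export
length.gaze_series <- function(x) length(x$x)

#' @export
print.gaze_series <- function(x, ...) {
  n <- length(x$x)
  nmiss <- sum(!is.finite(x$x))
  cat(sprintf(
    "<gaze_series> %d samples @ %g Hz (%.2f s), px2deg=%g, %d missing (%.1f%%)\n",
    n, x$sampling_rate, n / x$sampling_rate, x$px2deg,
    nmiss, 100 * nmiss / n))
  invisible(x)
}

#' Missing-sample mask of a gaze series
#'
#' @param series A [gaze_series()].
#' @return Logical vector, `TRUE` where the sample is missing.
#' @export
gaze_missing <- function(series) {
  !is.finite(series$x) | !is.finite(series$y)
}

# seconds -> samples; optionally forced odd (symmetric filter windows)
sec2samp <- function(duration, sampling_rate, odd = FALSE, minimum = 0L) {
  n <- as.integer(round(duration * sampling_rate))
  if (odd && n %% 2L == 0L) n <- n + 1L
  max(n, minimum)
}

#' Construct a per-sample velocity series
#'
#' Internal representation of per-sample angular gaze speed aligned with its
#' source [gaze_series()].  The first sample carries the velocity of the
#' displacement leading into it (forward difference assigned to the later
#' sample); sample 1 is therefore always masked.
#'
#' @param v Numeric vector of angular speeds (deg/s); `NA` where masked.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `velocity_series` with elements `v`, `mask`
#'   (logical, `TRUE` = missing/unusable) and `sampling_rate`.
#' @export
velocity_series <- function(v, sampling_rate) {
  v <- as.numeric(v)
  structure(
    list(v = v, mask = !is.finite(v), sampling_rate = as.numeric(sampling_rate)),
    class = "velocity_series")
}

#' @export
length.velocity_series <- function(x) length(x$v)

#' @export
print.velocity_series <- function(x, ...) {
  fin <- x$v[is.finite(x$v)]
  cat(sprintf(
    "<velocity_series> %d samples @ %g Hz, median %.2f deg/s, max %.2f deg/s, %d masked\n",
    length(x$v), x$sampling_rate,
    if (length(fin)) stats::median(fin) else NA_real_,
    if (length(fin)) max(fin) else NA_real_,
    sum(x$mask)))
  invisible(x)
}
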