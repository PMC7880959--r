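#' Remove single-sample coordinate spikes
#'
#' Heuristic spike filter applied independently per coordinate axis.  A sample
#' is treated as a spike if it is a strict local extremum relative to its two
#' neighbors and its distance to each neighbor exceeds the distance between
#' the neighbors themselves; such a sample is replaced by the value of the
#' nearer neighbor (ties resolved toward the preceding one).  Two-sample or
#' longer excursions are left untouched, as are missing samples.
#'
#' @param series A [gaze_series()].
#' @return A [gaze_series()] of identical length.
#' @export
filter_spikes <- function(series) {
  n <- length(series$x)
  if (n < 3L) return(series)
  series$x <- despike_axis(series$x)
  series$y <- despike_axis(series$y)
  series
}

despike_axis <- function(x) {
  n <- length(x)
  i <- 2:(n - 1L)
  x1 <- x[i - 1L]; x2 <- x[i]; x3 <- x[i + 1L]
  d13 <- abs(x3 - x1)
  spike <- (x2 > pmax(x1, x3) | x2 < pmin(x1, x3)) &
    abs(x2 - x1) > d13 & abs(x2 - x3) > d13
  spike[!is.finite(spike)] <- FALSE
  repl <- ifelse(abs(x2 - x1) <= abs(x2 - x3), x1, x3)
  x[i][spike] <- repl[spike]
  x
}

#' Dilate signal-loss windows
#'
#' Extends every contiguous missing-data run of at least `min_blink_duration`
#' seconds by `dilate_nan` seconds of missing markers on both sides (clipped
#' at the series bounds).  Blinks produce movement artifacts while the eyelid
#' closes and re-opens; masking a margin around the loss window removes them
#' without shortening the time series.  Shorter dropouts are left untouched
#' and no sample is ever un-masked.  Loss windows are encoded as `NaN` and
#' the added margins as plain `NA` (both count as missing downstream), so
#' the operation is idempotent: margins never re-qualify as loss windows.
#'
#' @param series A [gaze_series()].
#' @param params A [gaze_params()] list (uses `min_blink_duration`,
#'   `dilate_nan`).
#' @return A [gaze_series()] of identical length.
#' @export
dilate_signal_loss <- function(series, params = gaze_params()) {
  # only true loss windows (NaN) qualify; plain-NA margins from an earlier
  # dilation pass do not, which makes the operation idempotent
  loss <- is.nan(series$x) | is.nan(series$y)
  if (!any(loss)) return(series)
  sr <- series$sampling_rate
  min_len <- params$min_blink_duration * sr   # runs shorter than this stay
  nd <- sec2samp(params$dilate_nan, sr)
  n <- length(loss)
  r <- rle(loss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  margin <- logical(n)
  for (k in which(r$values)) {
    if (r$lengths[k] >= min_len && nd > 0L) {
      lo <- max(1L, starts[k] - nd)
      hi <- min(n, ends[k] + nd)
      margin[lo:hi] <- TRUE
    }
  }
  margin <- margin & !loss
  series$x[margin] <- NA_real_
  series$y[margin] <- NA_real_
  series
}

# fill NAs for filtering, apply FUN to the filled trace, then re-propagate the
# missing marker to every output sample whose window touched a missing sample
filter_with_na <- function(x, width, FUN) {
  fin <- is.finite(x)
  if (!any(fin)) return(x)
  xf <- x
  if (!all(fin)) {
    idx <- which(fin)
    xf <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  }
  out <- FUN(xf)
  if (!all(fin)) {
    half <- (width - 1L) %/% 2L
    bad <- which(!fin)
    if (half > 0L) {
      touched <- unique(unlist(lapply(bad, function(i)
        max(1L, i - half):min(length(x), i + half))))
    } else touched <- bad
    out[touched] <- NA_real_
  }
  out
}

#' Running-median smoothing (chunking stream)
#'
#' Smooths both coordinate axes with a running median over
#' `median_filter_length` seconds.  The comparatively large window suppresses
#' noise and small eye movements while preserving the position steps of
#' large-amplitude saccades, which makes the resulting stream suitable for
#' coarse segmentation of the recording at major saccades.  Windows that
#' contain missing samples propagate the missing marker rather than
#' interpolating across signal loss.
#'
#' @inheritParams dilate_signal_loss
#' @return A [gaze_series()] of identical length.
#' @export
smooth_median <- function(series, params = gaze_params()) {
  k <- sec2samp(params$median_filter_length, series$sampling_rate,
                odd = TRUE, minimum = 1L)
  n <- length(series$x)
  if (k > n)
    stop("median filter window (", k, " samples) longer than series (", n, ")")
  if (k == 1L) return(series)
  med <- function(v) as.numeric(stats::runmed(v, k, endrule = "median"))
  series$x <- filter_with_na(series$x, k, med)
  series$y <- filter_with_na(series$y, k, med)
  series
}

#' Savitzky-Golay smoothing (classification stream)
#'
#' Least-squares local-polynomial smoothing of both coordinate axes with a
#' window of `savgol_length` seconds and polynomial order `savgol_polyord`.
#' All event classification other than the localization of major saccades is
#' performed on velocities derived from this stream.  Windows containing
#' missing samples propagate the missing marker.
#'
#' @inheritParams dilate_signal_loss
#' @return A [gaze_series()] of identical length.
#' @export
smooth_savgol <- function(series, params = gaze_params()) {
  k <- sec2samp(params$savgol_length, series$sampling_rate,
                odd = TRUE, minimum = 1L)
  if (params$savgol_polyord >= k)
    stop("savgol_polyord (", params$savgol_polyord,
         ") must be smaller than the filter window (", k, " samples)")
  n <- length(series$x)
  if (k > n)
    stop("Savitzky-Golay window (", k, " samples) longer than series (", n, ")")
  if (k == 1L) return(series)
  sg <- function(v) as.numeric(signal::sgolayfilt(v, p = params$savgol_polyord, n = k))
  series$x <- filter_with_na(series$x, k, sg)
  series$y <- filter_with_na(series$y, k, sg)
  series
}

#' Per-sample angular gaze velocity
#'
#' Computes angular speed as the Euclidean displacement between consecutive
#' samples scaled by `px2deg` and the sampling rate.  The forward difference
#' is assigned to the later sample; the first sample is masked.  Samples
#' adjacent to missing data are masked, and velocities exceeding `max_vel`
#' are clamped to `max_vel` with a warning (implausibly fast samples usually
#' indicate inappropriate filter settings for the noise level at hand).
#'
#' @inheritParams dilate_signal_loss
#' @param params A [gaze_params()] list (uses `max_vel`).
#' @return A [velocity_series()] aligned with `series`.
#' @export
compute_velocity <- function(series, params = gaze_params()) {
  if (series$px2deg <= 0 || series$sampling_rate <= 0)
    stop("px2deg and sampling_rate must be positive")
  dx <- diff(series$x)
  dy <- diff(series$y)
  v <- c(NA_real_, sqrt(dx^2 + dy^2) * series$px2deg * series$sampling_rate)
  over <- which(is.finite(v) & v > params$max_vel)
  if (length(over)) {
    warning(length(over), " velocity sample(s) exceeded max_vel (",
            params$max_vel, " deg/s) and were clamped; ",
            "filter settings may be inappropriate for this noise level")
    v[over] <- params$max_vel
  }
  velocity_series(v, series$sampling_rate)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: spike removal, signal-loss dilation, the two smoothing
#' branches (running median for chunking, Savitzky-Golay for event
#' classification), velocity computation and clamping.
#'
#' @inheritParams dilate_signal_loss
#' @param params A [gaze_params()] list.
#' @return A list with elements `med` and `sg` (smoothed [gaze_series()]),
#'   and `v_med` and `v_sg` (their [velocity_series()]).
#' @export
preprocess_gaze <- function(series, params = gaze_params()) {
  s <- filter_spikes(series)
  s <- dilate_signal_loss(s, params)
  med <- smooth_median(s, params)
  sg <- smooth_savgol(s, params)
  list(med = med, sg = sg,
       v_med = compute_velocity(med, params),
       v_sg = compute_velocity(sg, params))
}
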