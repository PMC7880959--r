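# convergence criterion of the iterative threshold update (deg/s); fixed by
# the algorithm definition, deliberately not a user parameter
VELTHRESH_CONVERGENCE <- 1
VELTHRESH_MAX_ITER <- 1000L

#' Adaptive saccade velocity threshold
#'
#' Iteratively estimates a data-driven saccade velocity threshold from a
#' velocity series.  Starting from `velthresh_startvelocity` (PT\[0\]), each
#' iteration collects the velocities strictly below the current threshold and
#' places the new threshold at
#' `median(V) + noise_factor * MAD(V)`,
#' where MAD is the raw median absolute deviation (no normality scaling).
#' Iteration stops when consecutive thresholds differ by less than 1 deg/s.
#' Median/MAD statistics make the update robust to the heavy right tail of
#' gaze velocity distributions, unlike the classical mean/SD update.
#'
#' If the sub-threshold set becomes empty or stops changing between
#' iterations, the previous threshold is returned (this guarantees
#' termination on degenerate data such as constant velocities).  A hard cap
#' of 1000 iterations triggers a warning.
#'
#' @param velocities A [velocity_series()] or numeric vector of velocities in
#'   deg/s (`NA` = masked).
#' @param params A [gaze_params()] list (uses `velthresh_startvelocity`,
#'   `noise_factor`).
#' @return A list of class `threshold_estimate` with elements `pt` (converged
#'   threshold, deg/s), `med` and `mad` (median and MAD of the final
#'   sub-threshold velocity context, deg/s), and `n_iter`.
#' @examples
#' est <- estimate_threshold(c(runif(500, 0, 20), 300, 400),
#'                           gaze_params(noise_factor = 5))
#' est$pt
#' @export
estimate_threshold <- function(velocities, params = gaze_params()) {
  v <- if (inherits(velocities, "velocity_series")) velocities$v else as.numeric(velocities)
  v <- v[is.finite(v)]
  if (length(v) < 2L)
    stop("threshold estimation needs at least 2 finite velocity samples")
  f <- params$noise_factor
  pt <- params$velthresh_startvelocity
  sub <- v[v < pt]
  if (length(sub) == 0L)
    stop("no finite velocity samples below the start velocity (",
         pt, " deg/s); cannot estimate a threshold")
  med <- mad <- NA_real_
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    med <- stats::median(sub)
    mad <- stats::median(abs(sub - med))
    pt_new <- med + f * mad
    if (abs(pt_new - pt) < VELTHRESH_CONVERGENCE) {
      pt <- pt_new
      break
    }
    nxt <- v[v < pt_new]
    if (length(nxt) == 0L || length(nxt) == length(sub)) {
      # degenerate: empty or unchanged sub-threshold set -> keep previous
      # threshold, whose context statistics are already in med/mad
      pt <- pt_new
      break
    }
    pt <- pt_new
    sub <- nxt
    if (n_iter >= VELTHRESH_MAX_ITER) {
      warning("velocity threshold estimation hit the iteration cap (",
              VELTHRESH_MAX_ITER, ") without converging")
      break
    }
  }
  structure(list(pt = pt, med = med, mad = mad, n_iter = n_iter),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf(
    "<threshold_estimate> pt=%.3f deg/s (median=%.3f, MAD=%.3f, %d iterations)\n",
    x$pt, x$med, x$mad, x$n_iter))
  invisible(x)
}

#' Saccade onset and peak velocity thresholds
#'
#' Derives the event-classification thresholds from a converged
#' [estimate_threshold()] context: the onset threshold is
#' `median + noise_factor * MAD`, the peak threshold uses twice the deviation
#' term (`median + 2 * noise_factor * MAD`).  Saccade peaks must exceed the
#' peak threshold; event on-/offsets are located where velocity falls to the
#' onset threshold.
#'
#' @param est A `threshold_estimate` from [estimate_threshold()].
#' @param params A [gaze_params()] list (uses `noise_factor`).
#' @return Named numeric vector with elements `onset` and `peak` (deg/s).
#' @export
derive_event_thresholds <- function(est, params = gaze_params()) {
  f <- params$noise_factor
  onset <- est$med + f * est$mad
  peak <- est$med + 2 * f * est$mad
  c(onset = onset, peak = peak)
}
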