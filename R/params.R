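#' Classifier parameters
#'
#' Assembles the complete parameter set of the event classifier with its
#' default values.  Defaults are tuned for typical remote/tower-mounted
#' eye-tracker recordings at 0.5-1 kHz and can be overridden individually.
#'
#' @param min_blink_duration Missing-data windows shorter than this duration
#'   (s) are not considered for `dilate_nan` dilation.  Default 0.02 s.
#' @param dilate_nan Duration (s) for which samples on either side of a
#'   qualifying signal-loss window are replaced by missing markers, to
#'   suppress eyelid-closure artifacts.  Default 0.01 s.
#' @param median_filter_length Window (s) of the running median filter used to
#'   build the coarse chunking stream that emphasizes large-amplitude
#'   saccades.  Default 0.05 s.
#' @param savgol_length Window (s) of the Savitzky-Golay noise-reduction
#'   filter on which all event classification is performed.  Default 0.019 s.
#' @param savgol_polyord Polynomial order of the Savitzky-Golay filter.
#'   Default 2.
#' @param max_vel Maximum plausible eye velocity (deg/s); faster samples are
#'   clamped to this value with a warning (biologically implausible
#'   measurements usually indicate inappropriate filter settings).
#'   Default 1000 deg/s.
#' @param min_saccade_duration Minimum duration (s) of a saccade candidate.
#'   Default 0.01 s.
#' @param max_pso_duration Maximum duration (s) of a post-saccadic
#'   oscillation.  Default 0.04 s.
#' @param min_fixation_duration Minimum duration (s) of a fixation candidate.
#'   Default 0.04 s.
#' @param min_pursuit_duration Minimum duration (s) of a pursuit candidate.
#'   Default 0.04 s.
#' @param min_intersaccade_duration No saccade classification is performed in
#'   windows shorter than twice this value plus the minimum saccade and
#'   maximum PSO durations; also the minimum separation between classified
#'   saccades.  Default 0.04 s.
#' @param noise_factor Scalar multiplier F of the median absolute deviation in
#'   the adaptive onset threshold (the peak threshold uses 2F); increase for
#'   noisy data to reduce false positives.  Default 5.
#' @param velthresh_startvelocity Start value (deg/s) of the iterative
#'   threshold estimation; should exceed any conceivable minimum saccade
#'   velocity.  Default 300 deg/s.
#' @param max_initial_saccade_freq Maximum average frequency (Hz) of major
#'   saccades accepted during initial chunking.  Default 2 Hz.
#' @param saccade_context_window_length Window (s) centered on a major
#'   saccade's velocity peak within which its thresholds are estimated.
#'   Default 1 s.
#' @param lowpass_cutoff_freq Cut-off (Hz) of the Butterworth low-pass filter
#'   applied to velocities before pursuit classification.  Default 4 Hz.
#' @param pursuit_velthresh Fixed drift-velocity threshold (deg/s) separating
#'   pursuit from fixation; should exceed natural ocular drift velocities.
#'   Default 2 deg/s.
#'
#' @return A list of class `gaze_params` with all parameters named as above.
#' @examples
#' p <- gaze_params(noise_factor = 3)
#' p$noise_factor
#' @export
gaze_params <- function(min_blink_duration = 0.02,
                        dilate_nan = 0.01,
                        median_filter_length = 0.05,
                        savgol_length = 0.019,
                        savgol_polyord = 2,
                        max_vel = 1000,
                        min_saccade_duration = 0.01,
                        max_pso_duration = 0.04,
                        min_fixation_duration = 0.04,
                        min_pursuit_duration = 0.04,
                        min_intersaccade_duration = 0.04,
                        noise_factor = 5,
                        velthresh_startvelocity = 300,
                        max_initial_saccade_freq = 2,
                        saccade_context_window_length = 1,
                        lowpass_cutoff_freq = 4,
                        pursuit_velthresh = 2) {
  p <- list(
    min_blink_duration = min_blink_duration,
    dilate_nan = dilate_nan,
    median_filter_length = median_filter_length,
    savgol_length = savgol_length,
    savgol_polyord = as.integer(savgol_polyord),
    max_vel = max_vel,
    min_saccade_duration = min_saccade_duration,
    max_pso_duration = max_pso_duration,
    min_fixation_duration = min_fixation_duration,
    min_pursuit_duration = min_pursuit_duration,
    min_intersaccade_duration = min_intersaccade_duration,
    noise_factor = noise_factor,
    velthresh_startvelocity = velthresh_startvelocity,
    max_initial_saccade_freq = max_initial_saccade_freq,
    saccade_context_window_length = saccade_context_window_length,
    lowpass_cutoff_freq = lowpass_cutoff_freq,
    pursuit_velthresh = pursuit_velthresh)
  validate_gaze_params(p)
  structure(p, class = "gaze_params")
}

validate_gaze_params <- function(p) {
  durs <- c("min_blink_duration", "dilate_nan", "median_filter_length",
            "savgol_length", "min_saccade_duration", "max_pso_duration",
            "min_fixation_duration", "min_pursuit_duration",
            "min_intersaccade_duration", "saccade_context_window_length")
  for (d in durs) {
    if (!is.numeric(p[[d]]) || length(p[[d]]) != 1L || !is.finite(p[[d]]) ||
        p[[d]] < 0)
      stop(sprintf("parameter '%s' must be a single non-negative duration (s)", d))
  }
  pos <- c("max_vel", "noise_factor", "velthresh_startvelocity",
           "max_initial_saccade_freq", "lowpass_cutoff_freq",
           "pursuit_velthresh")
  for (d in pos) {
    if (!is.numeric(p[[d]]) || length(p[[d]]) != 1L || !is.finite(p[[d]]) ||
        p[[d]] <= 0)
      stop(sprintf("parameter '%s' must be a single positive number", d))
  }
  if (p$savgol_polyord < 0)
    stop("savgol_polyord must be >= 0")
  invisible(p)
}

#' @export
print.gaze_params <- function(x, ...) {
  cat("<gaze_params>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %g\n", nm, x[[nm]]))
  invisible(x)
}
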