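#' Build a synthetic gaze recording script
#'
#' Creates an empty event script to which directives are appended with
#' [sg_fixation()], [sg_saccade()], [sg_pso()], [sg_pursuit()] and
#' [sg_blink()].  [generate_recording()] turns the script into a
#' [gaze_series()] with sample-level ground truth.  Generation is fully
#' deterministic given `seed`; the global random generator state is left
#' untouched.
#'
#' Saccade kinematics follow the main-sequence relationship between
#' amplitude and peak velocity, `peak_vel = main_seq_k * amplitude^main_seq_m`
#' (deg/s), with a raised-cosine displacement profile.  Scripts implying
#' peak velocities above `vel_cap` are rejected at generation time.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param px2deg Degrees of visual angle per pixel.
#' @param noise_sd Gaussian coordinate noise SD in pixels.
#' @param noise_profile Piecewise-constant noise multipliers; the recording
#'   is split into `length(noise_profile)` equal spans, span `k` receiving
#'   noise SD `noise_sd * noise_profile[k]`.
#' @param seed Integer seed for the generator's private random stream.
#' @param start_x,start_y Initial gaze position in pixels.
#' @param main_seq_k,main_seq_m Main-sequence constants (deg/s at 1 deg, and
#'   exponent).
#' @param vel_cap Physiological peak-velocity cap in deg/s.
#' @return An object of class `gaze_script`.
#' @examples
#' sc <- gaze_script(seed = 1)
#' sc <- sg_fixation(sc, duration = 1)
#' sc <- sg_saccade(sc, amplitude = 5)
#' sc <- sg_pso(sc)
#' sc <- sg_fixation(sc, duration = 1)
#' rec <- generate_recording(sc)
#' @export
gaze_script <- function(sampling_rate = 1000, px2deg = 0.0177,
                        noise_sd = 0.1, noise_profile = 1, seed = 1,
                        start_x = 960, start_y = 540,
                        main_seq_k = 80, main_seq_m = 0.6,
                        vel_cap = 1200) {
  stopifnot(sampling_rate > 0, px2deg > 0, noise_sd >= 0,
            all(noise_profile >= 0), length(noise_profile) >= 1)
  structure(
    list(sampling_rate = sampling_rate, px2deg = px2deg,
         noise_sd = noise_sd, noise_profile = noise_profile,
         seed = as.integer(seed), start_x = start_x, start_y = start_y,
         main_seq_k = main_seq_k, main_seq_m = main_seq_m,
         vel_cap = vel_cap, directives = list()),
    class = "gaze_script")
}

add_directive <- function(script, d) {
  stopifnot(inherits(script, "gaze_script"))
  script$directives[[length(script$directives) + 1L]] <- d
  script
}

#' @rdname gaze_script
#' @param script A `gaze_script`.
#' @param duration Event duration in seconds (> 0).
#' @param drift_vel Root-mean-square speed (deg/s) of the slow, wandering
#'   ocular drift during the fixation, modeled as a two-dimensional
#'   Ornstein-Uhlenbeck velocity process with a 0.1-s correlation time.
#' @export
sg_fixation <- function(script, duration, drift_vel = 0.8) {
  stopifnot(duration > 0, drift_vel >= 0)
  add_directive(script, list(type = "fixation", duration = duration,
                             drift_vel = drift_vel))
}

#' @rdname gaze_script
#' @param amplitude Saccade amplitude in degrees (> 0).
#' @export
sg_saccade <- function(script, amplitude, direction = NULL) {
  stopifnot(amplitude > 0)
  add_directive(script, list(type = "saccade", amplitude = amplitude,
                             direction = direction))
}

#' @rdname gaze_script
#' @param relative_peak_fraction Peak velocity of the oscillation as a
#'   fraction of the preceding saccade's peak velocity.
#' @param max_peak_vel Saturation of the oscillation's peak velocity
#'   (deg/s); post-saccadic oscillations of the eyeball do not scale
#'   indefinitely with saccade size.
#' @export
sg_pso <- function(script, relative_peak_fraction = 0.06, duration = 0.035,
                   max_peak_vel = 12) {
  stopifnot(relative_peak_fraction > 0, duration > 0, max_peak_vel > 0)
  nd <- length(script$directives)
  if (nd == 0L || script$directives[[nd]]$type != "saccade")
    stop("a pso directive must immediately follow a saccade directive")
  add_directive(script, list(type = "pso",
                             relative_peak_fraction = relative_peak_fraction,
                             duration = duration,
                             max_peak_vel = max_peak_vel))
}

#' @rdname gaze_script
#' @param velocity Pursuit velocity in deg/s (should exceed the classifier's
#'   pursuit threshold to be recoverable).
#' @export
sg_pursuit <- function(script, duration, velocity = 5, direction = NULL) {
  stopifnot(duration > 0, velocity > 0)
  add_directive(script, list(type = "pursuit", duration = duration,
                             velocity = velocity, direction = direction))
}

#' @rdname gaze_script
#' @export
sg_blink <- function(script, duration = 0.1) {
  stopifnot(duration > 0)
  add_directive(script, list(type = "blink", duration = duration))
}

#' @export
print.gaze_script <- function(x, ...) {
  cat(sprintf("<gaze_script> %d directives @ %g Hz, noise_sd=%g px, seed=%d\n",
              length(x$directives), x$sampling_rate, x$noise_sd, x$seed))
  invisible(x)
}

# run expr with a private RNG stream; global .Random.seed is restored
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic gaze recording with ground truth
#'
#' Renders a [gaze_script()] into a pixel-coordinate [gaze_series()]:
#' fixations are stationary points with slow drift, saccades are smooth
#' raised-cosine displacements whose peak velocity follows the script's
#' main-sequence rule, post-saccadic oscillations are exponentially damped
#' sinusoids appended to the saccade offset, pursuits are constant-velocity
#' ramps, and blinks are masked windows flanked by brief high-velocity
#' eyelid artifacts.  Gaussian coordinate noise with the script's (possibly
#' piecewise-varying) amplitude is added to all visible samples.
#'
#' Ground-truth labels use the collapsed vocabulary `FIXA`, `SACC`, `PSO`,
#' `PURS`, `BLINK`: the chunk-boundary/intra-chunk saccade distinction and
#' the low/high-velocity PSO split depend on classifier-internal thresholds,
#' not on the generated kinematics.
#'
#' @param script A [gaze_script()].
#' @return A list with `series` (a [gaze_series()]) and `truth`, itself a
#'   list with `labels` (per-sample character vector) and `events`
#'   (data.frame with `label`, `onset_sample`, `offset_sample`,
#'   `onset_time`, `offset_time`).
#' @export
generate_recording <- function(script) {
  stopifnot(inherits(script, "gaze_script"))
  if (!length(script$directives))
    stop("script contains no directives")
  with_private_seed(script$seed, generate_recording_impl(script))
}

generate_recording_impl <- function(script) {
  sr <- script$sampling_rate
  p2d <- script$px2deg
  pos <- c(script$start_x, script$start_y)
  home <- pos
  x <- numeric(0); y <- numeric(0)
  labels <- character(0)
  ev_lab <- character(0); ev_on <- integer(0); ev_off <- integer(0)
  last_sacc <- NULL  # direction unit vector and peak velocity, for PSOs

  pick_dir <- function(direction) {
    if (!is.null(direction)) return(direction * pi / 180)
    d <- sqrt(sum((pos - home)^2))
    if (d > 300) {
      atan2(home[2] - pos[2], home[1] - pos[1]) + stats::runif(1, -pi / 3, pi / 3)
    } else stats::runif(1, 0, 2 * pi)
  }
  emit <- function(dx, dy, lab) {
    # dx/dy: per-sample displacements in px; returns nothing, grows traces
    n0 <- length(x)
    px <- pos[1] + cumsum(dx)
    py <- pos[2] + cumsum(dy)
    x <<- c(x, px); y <<- c(y, py)
    pos <<- c(px[length(px)], py[length(py)])
    labels <<- c(labels, rep(lab, length(dx)))
    ev_lab <<- c(ev_lab, lab)
    ev_on <<- c(ev_on, n0 + 1L)
    ev_off <<- c(ev_off, n0 + length(dx))
  }

  for (d in script$directives) {
    switch(d$type,
      fixation = {
        ns <- max(2L, round(d$duration * sr))
        # wandering drift: per-axis OU velocity, RMS speed = drift_vel
        rho <- exp(-1 / (0.1 * sr))
        sig <- d$drift_vel / sqrt(2)
        innov <- sqrt(1 - rho^2)
        # drift starts from standstill (the eye has just stopped moving) and
        # relaxes into its stationary distribution
        vx <- stats::filter(stats::rnorm(ns, 0, sig * innov), rho,
                            method = "recursive", init = 0)
        vy <- stats::filter(stats::rnorm(ns, 0, sig * innov), rho,
                            method = "recursive", init = 0)
        emit(as.numeric(vx) / p2d / sr, as.numeric(vy) / p2d / sr, "FIXA")
        last_sacc <- NULL
      },
      saccade = {
        pv <- script$main_seq_k * d$amplitude^script$main_seq_m
        if (pv > script$vel_cap)
          stop("saccade of ", d$amplitude, " deg implies a peak velocity of ",
               round(pv), " deg/s, above the physiological cap (",
               script$vel_cap, " deg/s)")
        # minimum-jerk displacement profile: zero velocity and acceleration
        # at both ends; peak velocity = 1.875 * amplitude / duration
        dur <- 1.875 * d$amplitude / pv
        ns <- max(4L, round(dur * sr))
        th <- pick_dir(d$direction)
        tt <- seq_len(ns) / ns
        prof <- d$amplitude * (10 * tt^3 - 15 * tt^4 + 6 * tt^5) / p2d
        dpx <- diff(c(0, prof))
        emit(dpx * cos(th), dpx * sin(th), "SACC")
        last_sacc <- list(dir = c(cos(th), sin(th)), peak_vel = pv)
      },
      pso = {
        if (is.null(last_sacc))
          stop("pso directive without a preceding saccade")
        ns <- max(4L, round(d$duration * sr))
        freq <- 1 / d$duration   # one overshoot-return cycle
        tau <- d$duration
        pv <- min(d$relative_peak_fraction * last_sacc$peak_vel,
                  d$max_peak_vel)
        tt <- seq_len(ns) / sr
        # damped-sinusoid *velocity* profile: starts at zero (continuous with
        # the saccade end), overshoots against the saccade direction first
        vel <- -sin(2 * pi * freq * tt) * exp(-tt / tau)
        vel <- vel * pv / max(abs(vel))
        dpx <- vel / p2d / sr
        emit(dpx * last_sacc$dir[1], dpx * last_sacc$dir[2], "PSO")
        last_sacc <- NULL
      },
      pursuit = {
        ns <- max(2L, round(d$duration * sr))
        th <- pick_dir(d$direction)
        step <- d$velocity / p2d / sr
        emit(rep(step * cos(th), ns), rep(step * sin(th), ns), "PURS")
        last_sacc <- NULL
      },
      blink = {
        ns <- max(1L, round(d$duration * sr))
        nart <- 3L
        # eyelid artifact: fast ~0.7 deg downward excursion into the loss
        # window and back out of it as the lid re-opens
        art <- -0.7 / p2d * c(0.2, 0.55, 1.0)  # px offsets from gaze position
        n0 <- length(x)
        x <- c(x, rep(pos[1], nart), rep(NA_real_, ns), rep(pos[1], nart))
        y <- c(y, pos[2] + art, rep(NA_real_, ns), pos[2] + rev(art))
        labels <- c(labels, rep("BLINK", nart + ns + nart))
        ev_lab <- c(ev_lab, "BLINK")
        ev_on <- c(ev_on, n0 + 1L)
        ev_off <- c(ev_off, n0 + nart + ns + nart)
        last_sacc <- NULL
      },
      stop("unknown directive type: ", d$type))
  }

  n <- length(x)
  vis <- is.finite(x)
  if (script$noise_sd > 0) {
    prof <- script$noise_profile[pmin(length(script$noise_profile),
                                      ceiling(seq_len(n) / n *
                                              length(script$noise_profile)))]
    x[vis] <- x[vis] + stats::rnorm(sum(vis), 0, script$noise_sd * prof[vis])
    y[vis] <- y[vis] + stats::rnorm(sum(vis), 0, script$noise_sd * prof[vis])
  }
  events <- data.frame(label = ev_lab,
                       onset_sample = ev_on, offset_sample = ev_off,
                       onset_time = (ev_on - 1) / sr, offset_time = ev_off / sr,
                       stringsAsFactors = FALSE)
  list(series = gaze_series(x, y, sampling_rate = sr, px2deg = p2d),
       truth = list(labels = labels, events = events))
}
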