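# maximal runs of consecutive finite samples with v > thresh within [lo, hi];
# returns a data.frame with start/end/peak (argmax of v)/weight (sum of v)
runs_above <- function(v, thresh, lo = 1L, hi = length(v)) {
  idx <- lo:hi
  above <- is.finite(v[idx]) & v[idx] > thresh
  if (!any(above)) {
    return(data.frame(start = integer(), end = integer(),
                      peak = integer(), weight = numeric()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    a <- idx[starts[k]]; b <- idx[ends[k]]
    seg <- a:b
    p <- seg[which.max(v[seg])]
    data.frame(start = a, end = b, peak = p, weight = sum(v[seg]))
  })
  do.call(rbind, out)
}

#' Chunk a recording at its major saccades
#'
#' Splits a recording into intersaccadic intervals so that velocity
#' thresholds can later adapt to local noise conditions.  A global robust
#' threshold is estimated on the heavily median-filtered velocity stream
#' ([estimate_threshold()]; its derived peak threshold is applied), every
#' maximal run of consecutive above-threshold samples becomes a boundary
#' candidate weighted by the sum of its velocities, and candidates are
#' accepted in descending weight order (ties: earlier run first) until
#' accepting another would push the average rate of accepted events over the
#' whole recording duration beyond `max_initial_saccade_freq`.  Chunk
#' boundaries are the peak-velocity samples of the accepted runs.
#'
#' @param chunk_velocities A [velocity_series()] computed from the
#'   median-filtered coordinate stream.
#' @param params A [gaze_params()] list.
#' @return A list with `chunks` (data.frame of half-open `start`/`end` sample
#'   indices tiling the recording, with `bounded_left`/`bounded_right` flags),
#'   `major_peaks` (sorted sample indices), `runs` (accepted candidate runs,
#'   time-ordered), and `threshold` (the applied global peak threshold, or
#'   `NA` if estimation failed).
#' @export
chunk_recording <- function(chunk_velocities, params = gaze_params()) {
  v <- chunk_velocities$v
  n <- length(v)
  dur <- n / chunk_velocities$sampling_rate
  single <- function(msg) {
    warning("time series chunking: ", msg, "; using a single chunk")
    list(chunks = data.frame(start = 1L, end = n + 1L,
                             bounded_left = FALSE, bounded_right = FALSE),
         major_peaks = integer(),
         runs = data.frame(start = integer(), end = integer(),
                           peak = integer(), weight = numeric()),
         threshold = NA_real_)
  }
  est <- tryCatch(estimate_threshold(chunk_velocities, params),
                  error = function(e) NULL)
  if (is.null(est)) return(single("velocity threshold estimation failed"))
  thr <- derive_event_thresholds(est, params)[["peak"]]
  cand <- runs_above(v, thr)
  if (!nrow(cand)) return(single("no above-threshold candidate runs"))
  # greedy selection by descending weight, earlier run wins ties
  cand <- cand[order(-cand$weight, cand$start), , drop = FALSE]
  max_n <- floor(params$max_initial_saccade_freq * dur)
  acc <- cand[seq_len(min(nrow(cand), max_n)), , drop = FALSE]
  if (!nrow(acc)) return(single("saccade frequency cap admits no candidates"))
  acc <- acc[order(acc$start), , drop = FALSE]
  rownames(acc) <- NULL
  peaks <- acc$peak
  bnd <- c(1L, peaks, n + 1L)
  chunks <- data.frame(
    start = bnd[-length(bnd)],
    end = bnd[-1],
    bounded_left = c(FALSE, rep(TRUE, length(peaks))),
    bounded_right = c(rep(TRUE, length(peaks)), FALSE))
  chunks <- chunks[chunks$end > chunks$start, , drop = FALSE]
  rownames(chunks) <- NULL
  list(chunks = chunks, major_peaks = peaks, runs = acc, threshold = thr)
}

#' Locate saccade on-/offset around a velocity peak
#'
#' Walks outward from the peak sample in both directions and returns the
#' nearest local velocity minima whose values do not exceed the onset
#' threshold: once velocity first drops to or below the threshold the walk
#' continues while velocity keeps strictly decreasing, so intermediate local
#' minima that stay above the threshold (e.g. between merged velocity pulses)
#' are skipped.  The search never crosses masked samples or the `lo`/`hi`
#' limits; a bound that had to be clamped there is flagged.
#'
#' @param velocities A [velocity_series()] or numeric velocity vector.
#' @param peak_index Sample index of the velocity peak.
#' @param onset_threshold Onset velocity threshold (deg/s).
#' @param lo,hi Sample index limits of the search context.
#' @return A list with `onset`, `offset` (sample indices bracketing the
#'   peak) and logical flags `clamped_onset`, `clamped_offset`.
#' @export
find_saccade_bounds <- function(velocities, peak_index, onset_threshold,
                                lo = 1L, hi = NULL) {
  v <- if (inherits(velocities, "velocity_series")) velocities$v else velocities
  if (is.null(hi)) hi <- length(v)
  walk <- function(from, step, lim) {
    j <- from
    repeat {
      nxt <- j + step
      if ((step < 0L && nxt < lim) || (step > 0L && nxt > lim) ||
          !is.finite(v[nxt]))
        return(list(idx = j, clamped = TRUE))
      j <- nxt
      if (v[j] <= onset_threshold) {
        # inside the sub-threshold region: continue to the local minimum
        repeat {
          nxt <- j + step
          if ((step < 0L && nxt < lim) || (step > 0L && nxt > lim) ||
              !is.finite(v[nxt]) || v[nxt] >= v[j])
            return(list(idx = j, clamped = FALSE))
          j <- nxt
        }
      }
    }
  }
  l <- walk(peak_index, -1L, lo)
  r <- walk(peak_index, +1L, hi)
  list(onset = l$idx, offset = r$idx,
       clamped_onset = l$clamped, clamped_offset = r$clamped)
}

#' Classify a post-saccadic oscillation following a saccade
#'
#' Searches the `max_pso_duration` window after a saccade offset for
#' velocities that re-exceed the saccade onset threshold.  If found, a PSO
#' event starting at the saccade offset is returned; its offset is the local
#' velocity minimum after the oscillation peak (same rule as for saccades),
#' clamped so that the PSO never outlasts the window.  The event is labeled
#' high-velocity (HPSO/IHPS) if the oscillation also exceeds the peak
#' threshold, low-velocity (LPSO/ILPS) otherwise; chunk-boundary saccades
#' yield HPSO/LPSO, intra-chunk saccades IHPS/ILPS.
#'
#' @param velocities A [velocity_series()] or numeric velocity vector.
#' @param saccade_offset Sample index of the parent saccade's offset.
#' @param onset_threshold,peak_threshold Thresholds (deg/s) of the parent
#'   saccade's context.
#' @param params A [gaze_params()] list (uses `max_pso_duration`).
#' @param sampling_rate Sampling rate in Hz (taken from `velocities` if it is
#'   a [velocity_series()]).
#' @param hi Last sample index the PSO may extend to (e.g. segment end).
#' @param chunk_boundary Whether the parent saccade is a chunk-boundary
#'   saccade.
#' @return A list with `onset`, `offset` (sample indices; onset is the first
#'   sample after the saccade offset) and `label`, or `NULL` when no PSO is
#'   present (a normal outcome).
#' @export
classify_pso <- function(velocities, saccade_offset, onset_threshold,
                         peak_threshold, params = gaze_params(),
                         sampling_rate = NULL, hi = NULL,
                         chunk_boundary = TRUE) {
  if (inherits(velocities, "velocity_series")) {
    v <- velocities$v
    if (is.null(sampling_rate)) sampling_rate <- velocities$sampling_rate
  } else v <- velocities
  if (is.null(hi)) hi <- length(v)
  w <- sec2samp(params$max_pso_duration, sampling_rate)
  a <- saccade_offset + 1L
  b <- min(saccade_offset + w, hi, length(v))
  if (b < a) return(NULL)
  win <- a:b
  # stop at the first masked sample: a PSO may not span signal loss
  m <- which(!is.finite(v[win]))
  if (length(m)) {
    b <- win[m[1]] - 1L
    if (b < a) return(NULL)
    win <- a:b
  }
  lobes <- runs_above(v, onset_threshold, a, b)
  if (!nrow(lobes)) return(NULL)
  # the oscillation lasts until its last above-threshold excursion settles:
  # walk to the offset from the final lobe's peak
  last_peak <- lobes$peak[nrow(lobes)]
  bounds <- find_saccade_bounds(v, last_peak, onset_threshold, lo = a, hi = b)
  off <- bounds$offset
  lab <- if (max(v[a:off], na.rm = TRUE) > peak_threshold) {
    if (chunk_boundary) "HPSO" else "IHPS"
  } else {
    if (chunk_boundary) "LPSO" else "ILPS"
  }
  list(onset = a, offset = off, label = lab)
}

# internal: detect saccades (and their PSOs) inside a finite window [lo, hi]
# using thresholds estimated from the given context; peaks processed in
# descending velocity order; proximity and duration rules enforced.
# bounded_left/right: whether the window directly abuts an already classified
# saccadic event (then candidates must keep min_intersaccade_duration away).
detect_saccades_in_window <- function(v, sr, lo, hi, params,
                                      context = lo:hi,
                                      label = "ISAC",
                                      bounded_left = FALSE,
                                      bounded_right = FALSE,
                                      forced_peak = NULL) {
  est <- tryCatch(estimate_threshold(v[context], params),
                  error = function(e) NULL)
  if (is.null(est)) {
    warning("velocity threshold estimation failed in a ",
            if (label == "SACC") "saccade context window" else "time series chunk",
            "; no saccades classified there")
    return(list())
  }
  thr <- derive_event_thresholds(est, params)
  min_sacc <- sec2samp(params$min_saccade_duration, sr)
  min_isi <- sec2samp(params$min_intersaccade_duration, sr)
  if (is.null(forced_peak)) {
    cand <- runs_above(v, thr[["peak"]], lo, hi)
    if (!nrow(cand)) return(list())
    peaks <- cand$peak[order(-v[cand$peak], cand$peak)]
  } else {
    if (!is.finite(v[forced_peak]) || v[forced_peak] < thr[["peak"]])
      return(list())
    peaks <- forced_peak
  }
  taken <- matrix(numeric(0), ncol = 2)  # accepted [on, off] intervals
  out <- list()
  for (p in peaks) {
    if (nrow(taken) && any(p >= taken[, 1] & p <= taken[, 2])) next
    b <- find_saccade_bounds(v, p, thr[["onset"]], lo = lo, hi = hi)
    on <- b$onset; off <- b$offset
    if (off - on + 1L < min_sacc) next
    # intersaccadic proximity: keep a clear margin to other saccadic events
    if (nrow(taken) &&
        any(pmax(taken[, 1], on - min_isi) <= pmin(taken[, 2], off + min_isi)))
      next
    if (bounded_left && on - lo < min_isi) next
    if (bounded_right && hi - off < min_isi) next
    pso <- classify_pso(v, off, thr[["onset"]], thr[["peak"]], params,
                        sampling_rate = sr, hi = hi,
                        chunk_boundary = (label == "SACC"))
    ext_off <- if (is.null(pso)) off else pso$offset
    taken <- rbind(taken, c(on, ext_off))
    out[[length(out) + 1L]] <- list(onset = on, offset = off, label = label,
                                    pso = pso, thresholds = thr)
  }
  out
}

#' Classify intra-chunk saccades and their PSOs
#'
#' Detects saccades within an intersaccadic window using velocity thresholds
#' estimated from the whole window (the event context for intra-chunk
#' saccades, label ISAC).  Candidate peaks above the context peak threshold
#' are resolved to on-/offsets via [find_saccade_bounds()]; events shorter
#' than `min_saccade_duration` or violating the intersaccadic proximity rule
#' are rejected, and no search is performed at all in windows shorter than
#' twice `min_intersaccade_duration` plus the minimum saccade and maximum PSO
#' durations.  Each accepted saccade is checked for a following PSO.
#'
#' @param velocities A [velocity_series()] from the Savitzky-Golay stream.
#' @param lo,hi Sample bounds (inclusive) of the window; must not contain
#'   masked samples for meaningful results.
#' @param params A [gaze_params()] list.
#' @param bounded_left,bounded_right Whether the window abuts an already
#'   classified saccadic event on that side.
#' @return A list of event descriptors (`onset`, `offset`, `label`, `pso`).
#' @export
classify_saccades <- function(velocities, lo = 1L, hi = length(velocities),
                              params = gaze_params(),
                              bounded_left = FALSE, bounded_right = FALSE) {
  v <- velocities$v
  sr <- velocities$sampling_rate
  min_win <- 2 * params$min_intersaccade_duration +
    params$min_saccade_duration + params$max_pso_duration
  if ((hi - lo + 1L) / sr < min_win) return(list())
  detect_saccades_in_window(v, sr, lo, hi, params, context = lo:hi,
                            label = "ISAC",
                            bounded_left = bounded_left,
                            bounded_right = bounded_right)
}

#' Segment an unlabeled stretch into pursuit and fixation
#'
#' Low-pass filters the stretch's velocities with a zero-phase Butterworth
#' filter (order 2, cutoff `lowpass_cutoff_freq`) to isolate drift
#' velocities, then labels maximal runs exceeding `pursuit_velthresh` —
#' extended outward to the nearest local minima, same rule as for saccades —
#' as pursuit (PURS) if they last at least `min_pursuit_duration`.  All
#' residual sub-stretches of at least `min_fixation_duration` become
#' fixations (FIXA); shorter residuals yield no event.  Stretches too short
#' for stable zero-phase filtering are processed with unfiltered velocities
#' (with a warning).
#'
#' @param velocities A [velocity_series()] from the Savitzky-Golay stream.
#' @param lo,hi Sample bounds (inclusive) of the unlabeled stretch; samples
#'   must be finite.
#' @param params A [gaze_params()] list.
#' @return A list of event descriptors (`onset`, `offset`, `label`).
#' @export
classify_pursuit_fixation <- function(velocities, lo = 1L,
                                      hi = length(velocities),
                                      params = gaze_params()) {
  v <- velocities$v
  sr <- velocities$sampling_rate
  min_fix <- sec2samp(params$min_fixation_duration, sr)
  min_pur <- sec2samp(params$min_pursuit_duration, sr)
  nseg <- hi - lo + 1L
  if (nseg < min_fix) return(list())
  seg <- v[lo:hi]
  # zero-phase filtering needs enough samples for its edge padding
  if (nseg > 18L && params$lowpass_cutoff_freq < sr / 2) {
    bf <- signal::butter(2, params$lowpass_cutoff_freq / (sr / 2), type = "low")
    segf <- as.numeric(signal::filtfilt(bf, seg))
  } else {
    if (params$lowpass_cutoff_freq >= sr / 2)
      warning("lowpass_cutoff_freq at or above the Nyquist frequency; ",
              "using unfiltered velocities for pursuit classification")
    else
      warning("unlabeled stretch too short for stable low-pass filtering; ",
              "using unfiltered velocities")
    segf <- seg
  }
  cand <- runs_above(segf, params$pursuit_velthresh)
  intervals <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(nrow(cand))) {
    b <- find_saccade_bounds(segf, cand$peak[k], params$pursuit_velthresh,
                             lo = 1L, hi = nseg)
    intervals <- rbind(intervals, c(b$onset, b$offset))
  }
  # merge overlapping refined intervals
  purs <- matrix(numeric(0), ncol = 2)
  if (nrow(intervals)) {
    intervals <- intervals[order(intervals[, 1]), , drop = FALSE]
    cur <- intervals[1, ]
    for (k in seq_len(nrow(intervals))[-1]) {
      if (intervals[k, 1] <= cur[2] + 1) cur[2] <- max(cur[2], intervals[k, 2])
      else { purs <- rbind(purs, cur); cur <- intervals[k, ] }
    }
    purs <- rbind(purs, cur)
    purs <- purs[purs[, 2] - purs[, 1] + 1 >= min_pur, , drop = FALSE]
  }
  out <- list()
  for (k in seq_len(nrow(purs))) {
    out[[length(out) + 1L]] <- list(onset = as.integer(lo + purs[k, 1] - 1),
                                    offset = as.integer(lo + purs[k, 2] - 1),
                                    label = "PURS")
  }
  # residual sub-stretches become fixations if long enough
  covered <- rep(FALSE, nseg)
  for (k in seq_len(nrow(purs))) covered[purs[k, 1]:purs[k, 2]] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(!r$values)) {
    if (r$lengths[k] >= min_fix) {
      out[[length(out) + 1L]] <- list(onset = lo + starts[k] - 1L,
                                      offset = lo + ends[k] - 1L,
                                      label = "FIXA")
    }
  }
  out
}

#' Classify a gaze recording into eye-movement events
#'
#' Runs the full pipeline: preprocessing ([preprocess_gaze()]), time series
#' chunking at major saccades ([chunk_recording()]), saccade and PSO
#' classification with chunk-wise adaptive velocity thresholds, and pursuit/
#' fixation segmentation of the remaining signal.  Chunk-boundary saccades
#' (SACC) use a `saccade_context_window_length` window centered on their
#' velocity peak as threshold context; intra-chunk saccades (ISAC) use their
#' whole chunk.  Event boundaries never cross missing-data runs; each
#' contiguous finite stretch is processed independently.  The result is
#' deterministic for fixed input and parameters.
#'
#' @param series A [gaze_series()] with raw pixel coordinates.
#' @param params A [gaze_params()] list.
#' @return A `gaze_events` data.frame (see [compute_event_properties()] for
#'   columns), sorted by onset and pairwise non-overlapping.
#' @examples
#' rec <- generate_recording(
#'   sg_pursuit(sg_saccade(sg_fixation(gaze_script(seed = 7), 2), 8), 1.5))
#' ev <- classify_recording(rec$series)
#' table(ev$label)
#' @export
classify_recording <- function(series, params = gaze_params()) {
  stopifnot(inherits(series, "gaze_series"))
  validate_gaze_params(params)
  n <- length(series$x)
  sr <- series$sampling_rate
  if (all(gaze_missing(series))) {
    warning("input contains no usable samples; returning no events")
    return(as_gaze_events(list()))
  }
  pp <- preprocess_gaze(series, params)
  v <- pp$v_sg$v
  if (sum(is.finite(v)) < 2L) {
    warning("too few finite velocity samples after preprocessing; ",
            "returning no events")
    return(as_gaze_events(list()))
  }
  ck <- chunk_recording(pp$v_med, params)
  ctx_half <- sec2samp(params$saccade_context_window_length, sr) %/% 2L
  min_isi <- sec2samp(params$min_intersaccade_duration, sr)

  # --- chunk-boundary saccades (SACC) from their local context windows
  sacc <- list()   # descriptors with onset/offset/label/pso
  for (k in seq_len(nrow(ck$runs))) {
    run <- ck$runs[k, ]
    seg <- run$start:run$end
    finseg <- seg[is.finite(v[seg])]
    if (!length(finseg)) next
    p <- finseg[which.max(v[finseg])]
    ctx <- max(1L, p - ctx_half):min(n, p + ctx_half)
    # confine the event search to the finite stretch around the peak
    stretch <- finite_stretch(v, p, 1L, n)
    lo <- max(stretch[1], ctx[1]); hi <- min(stretch[2], ctx[length(ctx)])
    ev <- detect_saccades_in_window(v, sr, lo, hi, params, context = ctx,
                                    label = "SACC", forced_peak = p)
    if (!length(ev)) next
    e <- ev[[1]]
    # proximity to the previously accepted boundary event
    prev_off <- if (length(sacc)) max(vapply(sacc, function(s)
      if (is.null(s$pso)) s$offset else s$pso$offset, numeric(1))) else -Inf
    if (e$onset <= prev_off) next
    if (e$onset - prev_off < min_isi) next
    sacc[[length(sacc) + 1L]] <- e
  }

  # --- intersaccadic segments
  occupied <- lapply(sacc, function(s)
    c(s$onset, if (is.null(s$pso)) s$offset else s$pso$offset))
  bnd <- if (length(occupied)) do.call(rbind, occupied) else
    matrix(numeric(0), ncol = 2)
  seg_lo <- c(1L, as.integer(bnd[, 2] + 1L))
  seg_hi <- c(as.integer(bnd[, 1] - 1L), n)
  events <- sacc
  for (s in seq_along(seg_lo)) {
    a <- seg_lo[s]; b <- seg_hi[s]
    if (b < a) next
    bl <- s > 1L              # segment abuts a saccadic event on the left
    br <- s < length(seg_lo)  # ... on the right
    for (st in finite_stretches(v, a, b)) {
      isac <- classify_saccades(pp$v_sg, st[1], st[2], params,
                                bounded_left = bl && st[1] == a,
                                bounded_right = br && st[2] == b)
      events <- c(events, isac)
      # unlabeled sub-stretches between the intra-chunk saccadic events
      occ <- rep(FALSE, st[2] - st[1] + 1L)
      for (e in isac) {
        off <- if (is.null(e$pso)) e$offset else e$pso$offset
        occ[(e$onset - st[1] + 1L):(off - st[1] + 1L)] <- TRUE
      }
      r <- rle(occ)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(!r$values)) {
        events <- c(events,
                    classify_pursuit_fixation(pp$v_sg,
                                              st[1] + starts[k] - 1L,
                                              st[1] + ends[k] - 1L, params))
      }
    }
  }

  # --- materialize event property rows (saccades bring their PSO along)
  rows <- list()
  for (e in events) {
    row <- compute_event_properties(e$label, e$onset, e$offset, pp$sg,
                                    pp$v_sg, series$px2deg)
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    if (!is.null(e$pso)) {
      prow <- compute_event_properties(e$pso$label, e$pso$onset, e$pso$offset,
                                       pp$sg, pp$v_sg, series$px2deg)
      if (!is.null(prow)) rows[[length(rows) + 1L]] <- prow
    }
  }
  as_gaze_events(rows)
}

# [lo, hi] bounds of the maximal finite stretch of v containing index i
finite_stretch <- function(v, i, lo, hi) {
  a <- i
  while (a > lo && is.finite(v[a - 1L])) a <- a - 1L
  b <- i
  while (b < hi && is.finite(v[b + 1L])) b <- b + 1L
  c(a, b)
}

# list of [start, end] bounds of all maximal finite stretches within [a, b]
finite_stretches <- function(v, a, b) {
  fin <- is.finite(v[a:b])
  if (!any(fin)) return(list())
  r <- rle(fin)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lapply(which(r$values), function(k) c(a + starts[k] - 1L, a + ends[k] - 1L))
}
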