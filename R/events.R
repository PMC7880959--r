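# the classifier's event label vocabulary
EVENT_LABELS <- c("FIXA", "SACC", "ISAC", "HPSO", "IHPS", "LPSO", "ILPS", "PURS")

#' Compute the descriptive properties of one event
#'
#' Given fixed on-/offset sample indices, derives the serialized event
#' fields: onset/offset time in seconds from recording start, start/end
#' coordinates from the smoothed trace, amplitude (straight-line distance in
#' degrees), and peak/median/average velocity over the finite in-event
#' velocity samples.  An event covers samples `onset_idx..offset_idx`
#' (inclusive); its onset time is `(onset_idx - 1) / sampling_rate` and its
#' offset time `offset_idx / sampling_rate`, so abutting events share a
#' boundary time without overlapping.
#'
#' @param label Event label (one of FIXA, SACC, ISAC, HPSO, IHPS, LPSO, ILPS,
#'   PURS).
#' @param onset_idx,offset_idx First and last sample index of the event
#'   (1-based, inclusive).
#' @param coords A [gaze_series()] providing the smoothed coordinate trace.
#' @param velocities A [velocity_series()] aligned with `coords`.
#' @param px2deg Degrees per pixel.
#' @return A one-row `data.frame` with columns `label`, `onset_time`,
#'   `offset_time`, `onset_sample`, `offset_sample`, `start_x`, `start_y`,
#'   `end_x`, `end_y`, `amplitude`, `peak_vel`, `median_vel`, `avg_vel`, or
#'   `NULL` (with a warning) if the event window holds no finite velocity
#'   sample.
#' @export
compute_event_properties <- function(label, onset_idx, offset_idx, coords,
                                     velocities, px2deg = coords$px2deg) {
  stopifnot(offset_idx >= onset_idx)
  sr <- coords$sampling_rate
  vwin <- velocities$v[onset_idx:offset_idx]
  vwin <- vwin[is.finite(vwin)]
  if (length(vwin) == 0L) {
    warning("dropping ", label, " event at sample ", onset_idx,
            ": all in-event velocities are masked")
    return(NULL)
  }
  sx <- coords$x[onset_idx]; sy <- coords$y[onset_idx]
  ex <- coords$x[offset_idx]; ey <- coords$y[offset_idx]
  data.frame(
    label = label,
    onset_time = (onset_idx - 1) / sr,
    offset_time = offset_idx / sr,
    onset_sample = as.integer(onset_idx),
    offset_sample = as.integer(offset_idx),
    start_x = sx, start_y = sy, end_x = ex, end_y = ey,
    amplitude = px2deg * sqrt((ex - sx)^2 + (ey - sy)^2),
    peak_vel = max(vwin),
    median_vel = stats::median(vwin),
    avg_vel = mean(vwin),
    stringsAsFactors = FALSE)
}

# bind per-event rows into a sorted gaze_events frame
as_gaze_events <- function(rows) {
  if (length(rows) == 0L) {
    df <- data.frame(label = character(), onset_time = numeric(),
                     offset_time = numeric(), onset_sample = integer(),
                     offset_sample = integer(), start_x = numeric(),
                     start_y = numeric(), end_x = numeric(), end_y = numeric(),
                     amplitude = numeric(), peak_vel = numeric(),
                     median_vel = numeric(), avg_vel = numeric(),
                     stringsAsFactors = FALSE)
  } else {
    df <- do.call(rbind, rows)
    df <- df[order(df$onset_time), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("gaze_events", "data.frame")
  df
}

#' @export
print.gaze_events <- function(x, ...) {
  cat(sprintf("<gaze_events> %d events\n", nrow(x)))
  if (nrow(x)) {
    tab <- table(factor(x$label, levels = EVENT_LABELS))
    cat("  ", paste(sprintf("%s:%d", names(tab), tab), collapse = "  "), "\n")
  }
  NextMethod()
}

#' Collapse event sub-labels into their main categories
#'
#' Maps chunk-boundary and intra-chunk saccades (SACC/ISAC) to `SACC`, and
#' all post-saccadic oscillation sub-labels (HPSO/IHPS/LPSO/ILPS) to `PSO`,
#' leaving all other labels untouched.  This is the label vocabulary used for
#' comparison against per-sample reference labelings, which typically do not
#' distinguish the sub-categories.
#'
#' @param labels Character vector of event or sample labels.
#' @return Character vector of collapsed labels.
#' @export
collapse_labels <- function(labels) {
  labels[labels == "ISAC"] <- "SACC"
  labels[labels %in% c("HPSO", "IHPS", "LPSO", "ILPS")] <- "PSO"
  labels
}

#' Rasterize events to per-sample labels
#'
#' Builds a per-sample label sequence from an event table: every sample
#' covered by an event receives the event's label, uncovered samples get
#' `fill`.
#'
#' @param events A `gaze_events` data.frame (needs `onset_sample`/
#'   `offset_sample`, or `onset_time`/`offset_time` with `sampling_rate`).
#' @param n_samples Length of the output sequence.
#' @param sampling_rate Sampling rate in Hz; required when sample index
#'   columns are absent.
#' @param fill Label assigned to samples not covered by any event.
#' @return Character vector of length `n_samples`.
#' @export
events_to_samples <- function(events, n_samples, sampling_rate = NULL,
                              fill = "NONE") {
  lab <- rep(fill, n_samples)
  if (!nrow(events)) return(lab)
  if (!is.null(events$onset_sample)) {
    on <- events$onset_sample
    off <- events$offset_sample
  } else {
    if (is.null(sampling_rate))
      stop("sampling_rate required when events carry no sample indices")
    on <- as.integer(round(events$onset_time * sampling_rate)) + 1L
    off <- as.integer(round(events$offset_time * sampling_rate))
  }
  for (i in seq_len(nrow(events))) {
    a <- max(1L, on[i]); b <- min(n_samples, off[i])
    if (b >= a) lab[a:b] <- events$label[i]
  }
  lab
}
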