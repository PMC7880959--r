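#' Read a gaze coordinate recording from a TSV file
#'
#' Reads dense fixed-rate gaze samples from tab-separated text, one sample
#' per line.  Only the first two columns are interpreted (as X and Y screen
#' coordinates in pixels); any further columns are ignored.  Any non-numeric
#' token (e.g. `nan`, `NA`, `.`, empty field) becomes a missing-sample
#' marker.
#'
#' @param path Path to the input file.
#' @param px2deg Degrees of visual angle per pixel.
#' @param sampling_rate Sampling rate in Hz.
#' @param skip_header If `TRUE`, the first line is skipped (input files are
#'   headerless by default).
#' @return A [gaze_series()].
#' @export
read_gaze <- function(path, px2deg, sampling_rate, skip_header = FALSE) {
  lines <- readLines(path)
  if (skip_header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("empty input file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad))
    stop("line ", bad[1] + as.integer(skip_header),
         " of ", path, " has fewer than 2 tab-separated columns")
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  gaze_series(x, y, sampling_rate = sampling_rate, px2deg = px2deg)
}

#' Write a gaze coordinate recording to a TSV file
#'
#' Serializes a [gaze_series()] in the dialect read by [read_gaze()]:
#' headerless, tab-separated, X and Y pixel coordinates, missing samples as
#' `nan`.
#'
#' @param series A [gaze_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gaze <- function(series, path) {
  fmt <- function(v) ifelse(is.finite(v), formatC(v, format = "f", digits = 3),
                            "nan")
  writeLines(paste(fmt(series$x), fmt(series$y), sep = "\t"), path)
  invisible(path)
}

#' Write classified events as a BIDS-style events table
#'
#' Serializes events as a tab-separated table with a header line and one
#' event per line, in the BIDS events dialect: `onset` and `duration` in
#' seconds (the offset is recoverable as their sum), followed by the event
#' label and its property columns `start_x`, `start_y`, `end_x`, `end_y`,
#' `amp` (deg), `peak_vel`, `med_vel`, `avg_vel` (deg/s).  Seconds,
#' coordinates and amplitudes are written with 3 decimals, velocities
#' with 2.
#'
#' @param events A `gaze_events` data.frame from [classify_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  f3 <- function(v) formatC(v, format = "f", digits = 3)
  f2 <- function(v) formatC(v, format = "f", digits = 2)
  header <- paste(c("onset", "duration", "label", "start_x", "start_y",
                    "end_x", "end_y", "amp", "peak_vel", "med_vel",
                    "avg_vel"), collapse = "\t")
  if (!nrow(events)) {
    writeLines(header, path)
    return(invisible(path))
  }
  rows <- paste(
    f3(events$onset_time),
    f3(events$offset_time - events$onset_time),
    events$label,
    f3(events$start_x), f3(events$start_y),
    f3(events$end_x), f3(events$end_y),
    f3(events$amplitude),
    f2(events$peak_vel), f2(events$median_vel), f2(events$avg_vel),
    sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an events table written by [write_events()]
#'
#' @param path Path to a tab-separated events table with `onset`, `duration`
#'   and `label` columns.
#' @return A data.frame with at least `onset`, `duration`, `label`, plus an
#'   `offset` column (`onset + duration`).
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("onset", "duration", "label") %in% names(df)))
    stop("not an events table (needs onset/duration/label columns): ", path)
  df$offset <- df$onset + df$duration
  df
}

#' Read and write per-sample label sequences
#'
#' Per-sample label files are tab-separated with a header and two columns:
#' `sample` (1-based index) and `label`.
#'
#' @param path File path.
#' @return For `read_labels`, a character vector of labels in sample order.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("sample", "label") %in% names(df)))
    stop("not a label table (needs sample/label columns): ", path)
  df$label[order(df$sample)]
}

#' @rdname read_labels
#' @param labels Character vector of per-sample labels.
#' @export
write_labels <- function(labels, path) {
  writeLines(c("sample\tlabel",
               paste(seq_along(labels), labels, sep = "\t")), path)
  invisible(path)
}
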