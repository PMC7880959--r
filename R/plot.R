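EVENT_COLORS <- c(FIXA = "#2ca02c55", SACC = "#1f77b455", ISAC = "#17becf55",
                  HPSO = "#5b2d8e55", IHPS = "#7b4bb055",
                  LPSO = "#b77fd655", ILPS = "#d3aee855",
                  PURS = "#d2b48c75")

#' Render a diagnostic classification figure
#'
#' Plots the gaze coordinate traces and the velocity time course with the
#' classified events as per-label shaded segments, and saves the figure to a
#' file (PNG, SVG or PDF, chosen by file extension).  Intended for visual
#' quality control of preprocessing and classification parameterization on
#' every processed recording.  Plotting failures are downgraded to warnings.
#'
#' @param series A [gaze_series()] (typically the smoothed classification
#'   stream).
#' @param velocities The matching [velocity_series()].
#' @param events A `gaze_events` data.frame.
#' @param path Output figure path (`.png`, `.svg`, or `.pdf`).
#' @return `path` invisibly, or `NULL` if plotting failed.
#' @export
render_diagnostics <- function(series, velocities, events, path) {
  tryCatch({
    ext <- tolower(tools::file_ext(path))
    switch(ext,
           png = grDevices::png(path, width = 1600, height = 800, res = 120),
           svg = grDevices::svg(path, width = 14, height = 7),
           pdf = grDevices::pdf(path, width = 14, height = 7),
           grDevices::png(path, width = 1600, height = 800, res = 120))
    on.exit(grDevices::dev.off())
    n <- length(series$x)
    tt <- seq_len(n) / series$sampling_rate
    op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
    on.exit(graphics::par(op), add = TRUE)
    shade <- function(ylim) {
      if (!nrow(events)) return()
      graphics::rect(events$onset_time, ylim[1], events$offset_time, ylim[2],
                     col = EVENT_COLORS[events$label], border = NA)
    }
    rng <- range(c(series$x, series$y), finite = TRUE)
    graphics::plot(NA, xlim = range(tt), ylim = rng, xlab = "",
                   ylab = "gaze position [px]")
    shade(rng)
    graphics::lines(tt, series$x, col = "black", lwd = 0.8)
    graphics::lines(tt, series$y, col = "grey40", lwd = 0.8)
    graphics::legend("topright",
                     legend = names(EVENT_COLORS),
                     fill = EVENT_COLORS, border = NA, ncol = 4,
                     cex = 0.7, bg = "white")
    vr <- range(velocities$v, finite = TRUE)
    if (!all(is.finite(vr))) vr <- c(0, 1)
    graphics::plot(NA, xlim = range(tt), ylim = vr, xlab = "time [s]",
                   ylab = "velocity [deg/s]")
    shade(vr)
    graphics::lines(tt, velocities$v, col = "grey20", lwd = 0.8)
    invisible(path)
  }, error = function(e) {
    warning("diagnostic figure could not be rendered: ", conditionMessage(e))
    NULL
  })
}
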