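#' Diagnostic event-window plot
#'
#' Base-graphics rendition of the 30-s integrated-visualization view used to
#' eyeball candidate jerks: the raw center-point velocity trace on a 0-60
#' cm/s scale with the burst band, plus per-sample rugs for the movement
#' state, Multi Conditions 1/2, the mobility state, and shaded spans for
#' detected events.
#'
#' @param series A [tracking_series()].
#' @param cfg A [detection_config()].
#' @param center_s Center of the plotted window, s.
#' @param span_s Window width, s (default 30).
#' @param events Optional classified event table to overlay.
#' @param signals Optional pre-computed [detection_signals()].
#' @return Invisibly, the sample index range plotted.
#' @export
plot_event_window <- function(series, cfg = detection_config(), center_s,
                              span_s = 30, events = NULL, signals = NULL) {
  sig <- signals %||% attr(events, "signals") %||% detection_signals(series, cfg)
  ser <- sig$series
  i <- which(ser$t >= center_s - span_s / 2 & ser$t <= center_s + span_s / 2)
  if (!length(i)) stop("window contains no samples")
  v <- as.numeric(sig$velocity)[i]
  graphics::plot(ser$t[i], v, type = "l", col = "grey20",
                 xlab = "time (s)", ylab = "center-point velocity (cm/s)",
                 ylim = c(-9, max(60, max(v, na.rm = TRUE))),
                 main = sprintf("%s @ %.0f s", ser$session_id, center_s))
  graphics::abline(h = c(cfg$burst_vel_min_cms, cfg$burst_vel_max_cms),
                   lty = 3, col = "firebrick")
  if (!is.null(events) && nrow(events)) {
    inwin <- events$offset_s >= min(ser$t[i]) & events$onset_s <= max(ser$t[i])
    for (k in which(inwin)) {
      col <- if (events$accepted[k] %in% TRUE) grDevices::adjustcolor("forestgreen", 0.25)
             else grDevices::adjustcolor("orange", 0.25)
      graphics::rect(events$onset_s[k], 0, events$offset_s[k], 60, col = col, border = NA)
    }
  }
  rug_row <- function(vals, y, col, label) {
    on <- i[which(vals[i] %in% TRUE)]
    if (length(on)) graphics::points(ser$t[on], rep(y, length(on)), pch = 15,
                                     cex = 0.3, col = col)
    graphics::mtext(label, side = 2, at = y, las = 2, cex = 0.6, line = 0.3)
  }
  rug_row(sig$moving, -2, "steelblue", "moving")
  rug_row(sig$mc1, -4, "purple", "MC1")
  rug_row(sig$mc2, -6, "darkorange", "MC2")
  imm <- sig$mobility_state == "Immobile"
  rug_row(imm, -8, "grey50", "immobile")
  invisible(range(i))
}
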