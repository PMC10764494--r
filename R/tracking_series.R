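#' Construct a tracking series
#'
#' A `tracking_series` holds one overhead video-tracking session of a single
#' mouse: per-sample time, the three tracked body points (center, nose,
#' tail-base) in centimetres, the two posture descriptors (body elongation in
#' percent, body bend angle in degrees), a per-sample missing mask and the
#' arena extent.
#'
#' @param session_id Character scalar identifying the session.
#' @param sample_rate_hz Sampling rate in samples per second.
#' @param t Numeric vector of per-sample times in seconds from recording start.
#' @param center,nose,tail Numeric n x 2 matrices of x/y coordinates in cm
#'   (origin at the arena's top-left corner as seen by the overhead camera,
#'   x to the right, y downwards).
#' @param elongation_pct Numeric vector, body elongation in percent (0 =
#'   circular blob, 100 = maximally stretched).
#' @param body_angle_deg Numeric vector, body bend angle in degrees (0 =
#'   straight body).
#' @param missing Logical vector marking samples where the tracker lost the
#'   animal. If `NULL`, inferred from `NA`s in the coordinate/posture fields.
#' @param arena_w_cm,arena_h_cm Arena extent in cm (default 30 x 30).
#'
#' @return An object of class `tracking_series`.
#' @seealso [read_tracking_table()], [validate_series()], [simulate_session()]
#' @export
tracking_series <- function(session_id, sample_rate_hz, t,
                            center, nose, tail,
                            elongation_pct, body_angle_deg,
                            missing = NULL,
                            arena_w_cm = 30, arena_h_cm = 30) {
  as_xy <- function(m, what) {
    m <- as.matrix(m)
    if (length(m) == 0L) m <- matrix(numeric(0), ncol = 2)
    if (ncol(m) != 2L)
      stop(sprintf("'%s' must be an n x 2 matrix of x/y coordinates", what))
    storage.mode(m) <- "double"
    colnames(m) <- c("x", "y")
    m
  }
  center <- as_xy(center, "center")
  nose <- as_xy(nose, "nose")
  tail <- as_xy(tail, "tail")
  n <- length(t)
  if (is.null(missing)) {
    missing <- rowSums(is.na(cbind(center, nose, tail,
                                   elongation_pct, body_angle_deg))) > 0
  }
  x <- structure(list(
    session_id = as.character(session_id),
    sample_rate_hz = as.numeric(sample_rate_hz),
    t = as.numeric(t),
    center = center, nose = nose, tail = tail,
    elongation_pct = as.numeric(elongation_pct),
    body_angle_deg = as.numeric(body_angle_deg),
    missing = as.logical(missing),
    arena_w_cm = as.numeric(arena_w_cm),
    arena_h_cm = as.numeric(arena_h_cm)
  ), class = "tracking_series")
  lens <- c(nrow(center), nrow(nose), nrow(tail),
            length(elongation_pct), length(body_angle_deg), length(missing))
  if (any(lens != n))
    stop("all per-sample fields must have the same length as 't'")
  if (!is.finite(x$sample_rate_hz) || x$sample_rate_hz <= 0)
    stop("'sample_rate_hz' must be a positive real")
  x
}

#' @export
length.tracking_series <- function(x) length(x$t)

#' @export
print.tracking_series <- function(x, ...) {
  n <- length(x)
  dur <- if (n > 0) x$t[n] - x$t[1] else 0
  cat(sprintf("<tracking_series> '%s': %d samples @ %.6g Hz (%.1f s), arena %g x %g cm, %d missing\n",
              x$session_id, n, x$sample_rate_hz, dur,
              x$arena_w_cm, x$arena_h_cm, sum(x$missing)))
  invisible(x)
}

#' @export
as.data.frame.tracking_series <- function(x, ...) {
  data.frame(
    time_s = x$t,
    center_x_cm = x$center[, 1], center_y_cm = x$center[, 2],
    nose_x_cm = x$nose[, 1], nose_y_cm = x$nose[, 2],
    tail_x_cm = x$tail[, 1], tail_y_cm = x$tail[, 2],
    elongation_pct = x$elongation_pct,
    body_angle_deg = x$body_angle_deg
  )
}

#' Validate a tracking series
#'
#' Checks every structural invariant of a [tracking_series()] and returns all
#' violations found rather than raising on the first one: strictly increasing
#' time at the stated sample rate (tolerance 1e-6 s), coordinates inside the
#' arena for non-missing samples, elongation in \[0, 100\], body angle in
#' \[0, 180\] and equal field lengths.
#'
#' @param series A `tracking_series`.
#' @return A data frame with columns `index` (first offending sample, `NA` for
#'   whole-series problems), `field` and `message`; zero rows iff the series
#'   is valid.
#' @export
validate_series <- function(series) {
  viol <- list()
  add <- function(index, field, message)
    viol[[length(viol) + 1L]] <<- data.frame(index = index, field = field,
                                             message = message)
  n <- length(series$t)
  lens <- c(center = nrow(series$center), nose = nrow(series$nose),
            tail = nrow(series$tail),
            elongation_pct = length(series$elongation_pct),
            body_angle_deg = length(series$body_angle_deg),
            missing = length(series$missing))
  for (f in names(lens))
    if (lens[[f]] != n)
      add(NA_integer_, f, sprintf("length %d differs from length(t) = %d",
                                  lens[[f]], n))
  if (n > 1) {
    dt <- diff(series$t)
    bad <- which(dt <= 0)
    if (length(bad))
      add(bad[1], "t", sprintf("time not strictly increasing at index %d", bad[1]))
    off <- which(abs(dt - 1 / series$sample_rate_hz) > 1e-6)
    if (length(off) && !length(bad))
      add(off[1], "t", sprintf("sample spacing deviates from 1/%g s at index %d",
                               series$sample_rate_hz, off[1]))
  }
  ok <- !series$missing
  in_arena <- function(m, w, h)
    m[, 1] >= 0 & m[, 1] <= w & m[, 2] >= 0 & m[, 2] <= h
  for (pt in c("center", "nose", "tail")) {
    if (lens[[pt]] != n) next
    bad <- which(ok & !in_arena(series[[pt]], series$arena_w_cm, series$arena_h_cm))
    if (length(bad))
      add(bad[1], pt, sprintf("%d sample(s) outside the %g x %g cm arena (first at index %d)",
                              length(bad), series$arena_w_cm, series$arena_h_cm, bad[1]))
  }
  if (lens[["elongation_pct"]] == n) {
    bad <- which(ok & (series$elongation_pct < 0 | series$elongation_pct > 100))
    if (length(bad))
      add(bad[1], "elongation_pct", sprintf("%d value(s) outside [0, 100] (first at index %d)",
                                            length(bad), bad[1]))
  }
  if (lens[["body_angle_deg"]] == n) {
    bad <- which(ok & (series$body_angle_deg < 0 | series$body_angle_deg > 180))
    if (length(bad))
      add(bad[1], "body_angle_deg", sprintf("%d value(s) outside [0, 180] (first at index %d)",
                                            length(bad), bad[1]))
  }
  if (length(viol)) do.call(rbind, viol)
  else data.frame(index = integer(0), field = character(0), message = character(0))
}

#' Per-sample signal aligned to a tracking series
#'
#' A thin numeric-vector class carrying a unit and the sampling rate, used for
#' velocity (cm/s), acceleration (cm/s^2) and mobility (%) traces.
#'
#' @param values Numeric vector.
#' @param unit Non-empty unit string, e.g. `"cm/s"`.
#' @param sample_rate_hz Sampling rate of the parent series.
#' @return An object of class `track_signal`.
#' @export
track_signal <- function(values, unit, sample_rate_hz) {
  if (!nzchar(unit)) stop("'unit' must be non-empty")
  structure(as.numeric(values), unit = unit,
            sample_rate_hz = as.numeric(sample_rate_hz),
            class = "track_signal")
}

#' @export
print.track_signal <- function(x, ...) {
  cat(sprintf("<track_signal> %d samples [%s] @ %g Hz\n",
              length(x), attr(x, "unit"), attr(x, "sample_rate_hz")))
  invisible(x)
}

signal_unit <- function(x) attr(x, "unit")
signal_rate <- function(x) attr(x, "sample_rate_hz")

# Rebuild a track_signal with new values, keeping unit/rate metadata.
signal_like <- function(values, template, unit = signal_unit(template)) {
  track_signal(values, unit, signal_rate(template))
}
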