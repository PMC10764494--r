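#' Per-sample velocity of a tracked body point
#'
#' Speed is the Euclidean displacement between consecutive samples multiplied
#' by the sampling rate, optionally boxcar-averaged. The analysis profile that
#' the detector reproduces uses the raw (1-sample averaging interval) velocity
#' of the center-point. The first sample's velocity is 0 so downstream state
#' machines have defined input from t = 0; samples adjacent to unresolved
#' tracking gaps yield `NA`.
#'
#' @param series A [tracking_series()], with gaps resolved via
#'   [interpolate_gaps()] if state logic is to be run downstream.
#' @param point One of `"center"`, `"nose"`, `"tail_base"`.
#' @param averaging_interval Boxcar window in samples (1 = raw).
#' @param despike Optional width (odd integer >= 3) of a median despike
#'   pre-filter applied to the raw speeds before averaging; `NULL` (default)
#'   disables it. This is a generic stand-in for undocumented proprietary
#'   outlier filters and is off for the reference analysis profile.
#' @return A [track_signal()] in cm/s.
#' @export
compute_velocity <- function(series, point = c("center", "nose", "tail_base"),
                             averaging_interval = 1L, despike = NULL) {
  point <- match.arg(point)
  if (averaging_interval < 1) stop("'averaging_interval' must be >= 1")
  m <- switch(point, center = series$center, nose = series$nose,
              tail_base = series$tail)
  n <- nrow(m)
  v <- numeric(n)
  if (n > 1) {
    d <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
    v[-1] <- d * series$sample_rate_hz
    na <- series$missing | is.na(m[, 1]) | is.na(m[, 2])
    v[-1][na[-1] | na[-n]] <- NA_real_
    v[1] <- 0
  }
  if (!is.null(despike)) v <- stats::runmed(v, max(3L, as.integer(despike)))
  sig <- track_signal(v, "cm/s", series$sample_rate_hz)
  if (averaging_interval > 1) sig <- sliding_average(sig, averaging_interval)
  sig
}

#' Per-sample acceleration magnitude
#'
#' Absolute velocity change between consecutive samples times the sampling
#' rate. The magnitude convention matches the multi-condition bound it feeds
#' (acceleration of the center-point below a maximum), which is a bound on
#' size, not direction. First sample is 0.
#'
#' @param velocity A velocity [track_signal()] in cm/s.
#' @param sample_rate_hz Sampling rate; defaults to the signal's own.
#' @return A [track_signal()] in cm/s^2.
#' @export
compute_acceleration <- function(velocity, sample_rate_hz = signal_rate(velocity)) {
  n <- length(velocity)
  a <- numeric(n)
  if (n > 1) a[-1] <- abs(diff(as.numeric(velocity))) * sample_rate_hz
  track_signal(a, "cm/s^2", sample_rate_hz)
}

#' Centered sliding (boxcar) average
#'
#' Mean over a centered window of `window` samples, truncated at the edges.
#' `NA` (missing) samples are excluded from each window's mean; a window with
#' no usable sample yields `NA`. For even windows the extra sample is taken
#' from the future side. `window = 1` is the identity.
#'
#' @param signal A [track_signal()] or numeric vector.
#' @param window Positive integer window length in samples.
#' @return Same type as `signal`.
#' @export
sliding_average <- function(signal, window) {
  window <- as.integer(window)
  if (is.na(window) || window < 1) stop("'window' must be a positive integer")
  x <- as.numeric(signal)
  n <- length(x)
  if (window == 1L || n == 0L) return(signal)
  lo <- (window - 1L) %/% 2L
  hi <- window - 1L - lo
  ok <- !is.na(x)
  cs <- cumsum(ifelse(ok, x, 0))
  cn <- cumsum(as.numeric(ok))
  i <- seq_len(n)
  iL <- pmax(1L, i - lo)
  iR <- pmin(n, i + hi)
  s <- cs[iR] - c(0, cs)[iL]
  k <- cn[iR] - c(0, cn)[iL]
  out <- s / k
  out[k == 0] <- NA_real_
  if (inherits(signal, "track_signal")) signal_like(out, signal) else out
}

#' Resolve short tracking gaps by linear interpolation
#'
#' Linearly interpolates all coordinate and posture fields across missing
#' spans no longer than `max_gap_s`; longer spans (and spans touching the
#' series edges) stay missing and render overlapping candidate windows
#' invalid during detection. The missing mask is updated. Gaps are never
#' interpolated at read time; this is the one explicit place they are
#' resolved.
#'
#' @param series A [tracking_series()].
#' @param max_gap_s Maximum gap length to bridge, in seconds.
#' @return A `tracking_series` with short gaps filled.
#' @export
interpolate_gaps <- function(series, max_gap_s = 1) {
  if (!any(series$missing)) return(series)
  max_len <- floor(max_gap_s * series$sample_rate_hz + 1e-9)
  r <- rle(series$missing)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n <- length(series$t)
  fill <- function(x, i0, i1) {
    # neighbours i0-1 and i1+1 are guaranteed present
    w <- (seq(i0, i1) - (i0 - 1L)) / (i1 + 1L - (i0 - 1L))
    x[i0:i1] <- x[i0 - 1L] * (1 - w) + x[i1 + 1L] * w
    x
  }
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    if (r$lengths[k] > max_len || i0 == 1L || i1 == n) next
    for (f in c("center", "nose", "tail")) {
      series[[f]][, 1] <- fill(series[[f]][, 1], i0, i1)
      series[[f]][, 2] <- fill(series[[f]][, 2], i0, i1)
    }
    series$elongation_pct <- fill(series$elongation_pct, i0, i1)
    series$body_angle_deg <- fill(series$body_angle_deg, i0, i1)
    series$missing[i0:i1] <- FALSE
  }
  series
}
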