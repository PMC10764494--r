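#' Hysteretic movement state
#'
#' Two-threshold moving/not-moving automaton: the state becomes Moving when
#' the velocity rises above `start_thr_cms`, becomes Not-moving when it falls
#' below `stop_thr_cms`, and otherwise holds its previous value. The initial
#' state is Not-moving; `NA` velocity samples hold the previous state. The
#' two thresholds of the reference profile (3.20 / 2.25 cm/s for the
#' center-point; 2.00 / 1.75 cm/s inside Multi Condition 2) follow this
#' start/stop semantics.
#'
#' @param velocity A velocity [track_signal()] in cm/s.
#' @param start_thr_cms Threshold to enter Moving (exclusive).
#' @param stop_thr_cms Threshold to exit Moving (exclusive); must be below
#'   `start_thr_cms`.
#' @return A logical vector (`TRUE` = Moving), one element per sample.
#' @export
movement_state <- function(velocity, start_thr_cms, stop_thr_cms) {
  if (stop_thr_cms >= start_thr_cms)
    stop("'stop_thr_cms' must be strictly below 'start_thr_cms'")
  v <- as.numeric(velocity)
  s <- rep(NA_real_, length(v))
  s[!is.na(v) & v > start_thr_cms] <- 1
  s[!is.na(v) & v < stop_thr_cms] <- 0
  # forward-fill holds (NA = "keep previous state"), initial state Not-moving
  known <- !is.na(s)
  filled <- c(0, s[known])[cumsum(known) + 1L]
  as.logical(filled)
}

#' Trajectory-based mobility surrogate
#'
#' Commercial trackers define mobility as the fraction of body pixels that
#' changed between frames; with only point trajectories available this
#' surrogate combines per-sample displacement of the three body points
#' (normalized by a body-length scale) with posture change:
#' `100 * min(1, w_c*d_center + w_n*d_nose + w_t*d_tail + w_e*|d elongation|/100)`
#' where each `d_p` is the point's displacement in cm divided by
#' `mob_body_len_cm`. When rendered video is available, [track_video()]
#' provides a pixel-change mobility instead; the detector accepts either
#' source.
#'
#' @param series A [tracking_series()] with gaps resolved.
#' @param cfg A [detection_config()] carrying the weights and length scale.
#' @return A [track_signal()] in percent (0-100); first sample 0.
#' @export
mobility_raw <- function(series, cfg = detection_config()) {
  n <- length(series$t)
  disp <- function(m) {
    d <- numeric(n)
    if (n > 1) d[-1] <- sqrt(diff(m[, 1])^2 + diff(m[, 2])^2)
    d
  }
  de <- numeric(n)
  if (n > 1) de[-1] <- abs(diff(series$elongation_pct))
  raw <- cfg$mob_w_center * disp(series$center) / cfg$mob_body_len_cm +
    cfg$mob_w_nose * disp(series$nose) / cfg$mob_body_len_cm +
    cfg$mob_w_tail * disp(series$tail) / cfg$mob_body_len_cm +
    cfg$mob_w_elong * de / 100
  raw[is.na(raw)] <- NA_real_
  track_signal(100 * pmin(1, raw), "%", series$sample_rate_hz)
}

#' Three-level mobility state
#'
#' Averages the mobility percentage over `mobility_window_samples` (centered
#' boxcar) and labels each sample: `HighlyMobile` above `mobility_high_pct`,
#' `Immobile` below `mobility_immobile_pct`, `Mobile` otherwise. Averaging is
#' applied before thresholding. `NA` mobility yields `NA` labels.
#'
#' @param mobility A mobility [track_signal()] in percent, from
#'   [mobility_raw()] or [track_video()].
#' @param cfg A [detection_config()].
#' @return A factor with levels `Immobile`, `Mobile`, `HighlyMobile`.
#' @export
mobility_state <- function(mobility, cfg = detection_config()) {
  m <- as.numeric(sliding_average(mobility, cfg$mobility_window_samples))
  lab <- ifelse(m > cfg$mobility_high_pct, "HighlyMobile",
                ifelse(m < cfg$mobility_immobile_pct, "Immobile", "Mobile"))
  factor(lab, levels = c("Immobile", "Mobile", "HighlyMobile"))
}

#' Multi Condition 1
#'
#' Per-sample conjunction over the center-point: movement state true
#' (hysteresis `move_start_cms`/`move_stop_cms`), velocity averaged over
#' `mc1_avg_window_samples` at most `mc1_avg_vel_max_cms`, body elongation at
#' most `mc1_elong_max_pct` and body angle at most `mc1_angle_max_deg`. The
#' apparent tension between "moving is true" and a tiny long-window average
#' velocity is deliberate: the conjunction selects an instantaneous spike
#' inside a long quiescent window, which is precisely the jerk signature.
#'
#' @param series A [tracking_series()] with gaps resolved.
#' @param cfg A [detection_config()].
#' @param velocity Optional pre-computed raw center velocity.
#' @return A logical vector, `NA` where inputs are missing.
#' @export
multi_condition_1 <- function(series, cfg = detection_config(), velocity = NULL) {
  v <- velocity %||% compute_velocity(series, "center", 1L)
  moving <- movement_state(v, cfg$move_start_cms, cfg$move_stop_cms)
  vavg <- as.numeric(sliding_average(v, cfg$mc1_avg_window_samples))
  moving & (vavg <= cfg$mc1_avg_vel_max_cms) &
    (series$elongation_pct <= cfg$mc1_elong_max_pct) &
    (series$body_angle_deg <= cfg$mc1_angle_max_deg)
}

#' Multi Condition 2
#'
#' Per-sample conjunction: center-point acceleration magnitude at most
#' `mc2_accel_max_cms2`, and movement state true simultaneously for
#' center-point, nose-point and tail-base with hysteresis thresholds
#' `mc2_move_start_cms`/`mc2_move_stop_cms`.
#'
#' @param series A [tracking_series()] with gaps resolved; nose and tail-base
#'   must not be entirely missing.
#' @param cfg A [detection_config()].
#' @param velocity Optional pre-computed raw center velocity.
#' @return A logical vector.
#' @export
multi_condition_2 <- function(series, cfg = detection_config(), velocity = NULL) {
  if (all(is.na(series$nose[, 1])) || all(is.na(series$tail[, 1])))
    stop("nose/tail-base entirely missing: Multi Condition 2 cannot be evaluated; ",
         "rerun detection in trajectory-only mode (use_mc2 = \"off\"), which ",
         "disables MC2 and flags it in the report")
  vc <- velocity %||% compute_velocity(series, "center", 1L)
  acc <- as.numeric(compute_acceleration(vc))
  mv <- function(pt, v = NULL) {
    v <- v %||% compute_velocity(series, pt, 1L)
    movement_state(v, cfg$mc2_move_start_cms, cfg$mc2_move_stop_cms)
  }
  (acc <= cfg$mc2_accel_max_cms2) & mv("center", vc) & mv("nose") & mv("tail_base")
}

#' All per-sample detection signals for one session
#'
#' Computes, in one pass, everything the event scan consumes: raw center
#' velocity, its 100-sample average, acceleration, the movement state, the
#' mobility trace and three-level state, Multi Conditions 1 and 2, and the
#' validity mask (samples not inside an unresolved tracking gap). Gaps up to
#' `interp_max_gap_s` are interpolated first.
#'
#' @param series A [tracking_series()].
#' @param cfg A [detection_config()].
#' @param mobility Optional externally supplied mobility [track_signal()]
#'   (e.g. pixel-change mobility from [track_video()]); defaults to the
#'   trajectory surrogate [mobility_raw()].
#' @param use_mc2 `"auto"` (disable MC2 only when nose/tail are entirely
#'   missing), `"on"`, or `"off"` (trajectory-only mode).
#' @return A list with elements `series` (gap-resolved), `velocity`, `accel`,
#'   `moving`, `mobility`, `mobility_state`, `mc1`, `mc2`, `mc2_enabled`,
#'   `valid`.
#' @export
detection_signals <- function(series, cfg = detection_config(), mobility = NULL,
                              use_mc2 = c("auto", "on", "off")) {
  use_mc2 <- match.arg(use_mc2)
  series <- interpolate_gaps(series, cfg$interp_max_gap_s)
  v <- compute_velocity(series, "center", 1L)
  mob <- mobility %||% mobility_raw(series, cfg)
  mc2_enabled <- switch(use_mc2,
    on = TRUE, off = FALSE,
    auto = !(all(is.na(series$nose[, 1])) || all(is.na(series$tail[, 1]))))
  mc2 <- if (mc2_enabled) multi_condition_2(series, cfg, v)
         else rep(FALSE, length(series$t))
  list(series = series,
       velocity = v,
       accel = compute_acceleration(v),
       moving = movement_state(v, cfg$move_start_cms, cfg$move_stop_cms),
       mobility = mob,
       mobility_state = mobility_state(mob, cfg),
       mc1 = multi_condition_1(series, cfg, v),
       mc2 = mc2,
       mc2_enabled = mc2_enabled,
       valid = !series$missing)
}
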