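#' Detection configuration
#'
#' Holds every numeric threshold of the analysis profile the detector
#' reproduces, plus the explicit window/burst parameters this package adds for
#' the profile's qualitative criteria ("short (1 s) burst", "long immobile
#' state", voluntary-movement rejection). Defaults are the published profile
#' values; everything is overridable for recalibration.
#'
#' @param move_start_cms,move_stop_cms Movement hysteresis thresholds for the
#'   center-point (enter Moving above start, exit below stop), cm/s.
#' @param mc1_avg_window_samples,mc1_avg_vel_max_cms Multi Condition 1:
#'   boxcar window (samples) and upper bound (cm/s) on the averaged
#'   center-point velocity.
#' @param mc1_elong_max_pct,mc1_angle_max_deg Multi Condition 1 upper bounds
#'   on body elongation (%) and body bend angle (deg).
#' @param mc2_accel_max_cms2 Multi Condition 2 upper bound on center-point
#'   acceleration magnitude, cm/s^2.
#' @param mc2_move_start_cms,mc2_move_stop_cms Multi Condition 2 movement
#'   hysteresis thresholds applied simultaneously to center, nose and
#'   tail-base, cm/s.
#' @param mobility_window_samples Mobility averaging window, samples.
#' @param mobility_high_pct,mobility_immobile_pct Three-level mobility
#'   thresholds: HighlyMobile above the first, Immobile below the second, %.
#' @param burst_vel_min_cms,burst_vel_max_cms Velocity band a myoclonic burst
#'   must reach (peak inside the band), cm/s.
#' @param burst_max_dur_s Maximum burst duration, s (operationalizes "short
#'   (1 s)" with margin for smoothing spread).
#' @param pre_immobile_min_s Minimum duration of the Immobile state that must
#'   end no more than 1 s before burst onset, s.
#' @param pair_min_gap_s,pair_max_gap_s Onset-gap interval within which two
#'   consecutive accepted events are flagged as a pair, s.
#' @param analysis_start_s,analysis_end_s Analysis window; the first recording
#'   hour is discarded and only the last three hours of a 4-h session are
#'   quantified.
#' @param start_latency_s Recording starts once the animal's center-point has
#'   been inside the arena for more than this many seconds (data-trim option).
#' @param merge_gap_s Velocity runs closer than this are merged into one
#'   candidate so a single jerk fragmented by smoothing is not double-counted.
#' @param mc_context_s Context around a burst (both sides) in which at least
#'   one Multi Condition hit is required, s.
#' @param pre_gap_max_s Maximum lag allowed between the end of the qualifying
#'   Immobile run and burst onset, s.
#' @param interp_max_gap_s Longest tracking gap resolved by interpolation, s;
#'   candidates overlapping longer gaps are rejected as unscorable.
#' @param walkin_window_s,walkin_frac Voluntary-movement rejection (i): reject
#'   if the mobility state was Mobile/HighlyMobile for more than
#'   `walkin_frac` of the `walkin_window_s` seconds before onset.
#' @param loco_net_disp_cm,loco_spike_factor,loco_ref_window_s Voluntary-
#'   movement rejection (ii): reject if net center displacement during the
#'   burst exceeds `loco_net_disp_cm` while no in-burst sample exceeds
#'   `loco_spike_factor` times the pre-burst velocity maximum over
#'   `loco_ref_window_s` seconds.
#' @param mob_w_center,mob_w_nose,mob_w_tail,mob_w_elong,mob_body_len_cm
#'   Weights and body-length scale of the trajectory-based mobility surrogate
#'   (see [mobility_raw()]).
#' @return An object of class `detection_config` (a named list).
#' @export
detection_config <- function(move_start_cms = 3.20, move_stop_cms = 2.25,
                             mc1_avg_window_samples = 100L,
                             mc1_avg_vel_max_cms = 0.45,
                             mc1_elong_max_pct = 75.00,
                             mc1_angle_max_deg = 20.00,
                             mc2_accel_max_cms2 = 180.00,
                             mc2_move_start_cms = 2.00,
                             mc2_move_stop_cms = 1.75,
                             mobility_window_samples = 15L,
                             mobility_high_pct = 60.00,
                             mobility_immobile_pct = 5.00,
                             burst_vel_min_cms = 20.0,
                             burst_vel_max_cms = 60.0,
                             burst_max_dur_s = 1.5,
                             pre_immobile_min_s = 10.0,
                             pair_min_gap_s = 1.0,
                             pair_max_gap_s = 20.0,
                             analysis_start_s = 3600,
                             analysis_end_s = 14400,
                             start_latency_s = 3.0,
                             merge_gap_s = 1.0,
                             mc_context_s = 0.2,
                             pre_gap_max_s = 1.0,
                             interp_max_gap_s = 1.0,
                             walkin_window_s = 5.0,
                             walkin_frac = 0.5,
                             loco_net_disp_cm = 10.0,
                             loco_spike_factor = 1.5,
                             loco_ref_window_s = 10.0,
                             mob_w_center = 0.3, mob_w_nose = 0.3,
                             mob_w_tail = 0.3, mob_w_elong = 0.1,
                             mob_body_len_cm = 7.0) {
  cfg <- as.list(environment())
  class(cfg) <- "detection_config"
  validate_detection_config(cfg)
  cfg
}

validate_detection_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("invalid detection config: ", msg)
  chk(cfg$move_stop_cms < cfg$move_start_cms,
      "move_stop_cms must be < move_start_cms")
  chk(cfg$mc2_move_stop_cms < cfg$mc2_move_start_cms,
      "mc2_move_stop_cms must be < mc2_move_start_cms")
  chk(cfg$mobility_immobile_pct < cfg$mobility_high_pct,
      "mobility_immobile_pct must be < mobility_high_pct")
  chk(cfg$burst_vel_min_cms < cfg$burst_vel_max_cms,
      "burst_vel_min_cms must be < burst_vel_max_cms")
  chk(cfg$analysis_start_s < cfg$analysis_end_s,
      "analysis_start_s must be < analysis_end_s")
  chk(cfg$mc1_avg_window_samples >= 1 && cfg$mobility_window_samples >= 1,
      "averaging windows must be >= 1 sample")
  chk(cfg$pair_min_gap_s < cfg$pair_max_gap_s,
      "pair_min_gap_s must be < pair_max_gap_s")
  invisible(cfg)
}

#' @export
print.detection_config <- function(x, ...) {
  cat("<detection_config>\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Read/write configuration YAML
#'
#' Configurations are exchanged as flat YAML maps. Unknown keys raise an
#' error; omitted keys take their defaults, so a written snapshot always
#' materializes every default and fully reproduces a run.
#'
#' @param path YAML file path.
#' @param cfg A [detection_config()] or [simulation_config()].
#' @return The configuration object, or `path` invisibly for the writers.
#' @export
read_detection_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(detection_config)))
  if (length(unknown))
    stop("unknown detection config key(s): ", paste(unknown, collapse = ", "))
  do.call(detection_config, vals)
}

#' @rdname read_detection_config
#' @export
write_detection_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname read_detection_config
#' @export
read_simulation_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(simulation_config)))
  if (length(unknown))
    stop("unknown simulation config key(s): ", paste(unknown, collapse = ", "))
  do.call(simulation_config, vals)
}

#' @rdname read_detection_config
#' @export
write_simulation_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
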