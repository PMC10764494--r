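#' Detect candidate myoclonic events
#'
#' Scans the analysis window for maximal runs of samples whose raw
#' center-point velocity exceeds `burst_vel_min_cms`. Runs separated by less
#' than `merge_gap_s` are merged (one jerk fragmented by smoothing must not
#' double-count); a merged run becomes a candidate iff
#'
#' \enumerate{
#'   \item its duration is at most `burst_max_dur_s`;
#'   \item its peak velocity lies inside
#'     `[burst_vel_min_cms, burst_vel_max_cms]`;
#'   \item the mobility state was Immobile for at least `pre_immobile_min_s`,
#'     ending no more than `pre_gap_max_s` before run onset (the "long
#'     immobile state" that precedes a sleep-time jerk, whose break is part
#'     of the signature);
#'   \item Multi Condition 1 and/or 2 is true at one or more samples within
#'     `mc_context_s` of the run.
#' }
#'
#' Candidates are returned sorted by onset with the `accepted` flag unset
#' (`NA`); [classify_events()] applies the voluntary-movement rejection.
#'
#' @param series A [tracking_series()].
#' @param cfg A [detection_config()]. Onsets are restricted to
#'   `[analysis_start_s, analysis_end_s]`; if the recording is shorter the
#'   window is clipped with a warning.
#' @param signals Optional pre-computed [detection_signals()].
#' @param ... Passed to [detection_signals()] (e.g. `use_mc2`, `mobility`).
#' @return A data frame of class `myoclonic_events`, one row per candidate:
#'   `onset_s`, `offset_s`, `onset_idx`, `offset_idx`, `peak_velocity_cms`,
#'   `pre_immobile_s`, `mc1_hit`, `mc2_hit`, `accepted`, `rejection_reason`,
#'   `pair_id`, `magnitude_class`. The gap-resolved signals are attached as
#'   attribute `"signals"` for downstream classification and plotting.
#' @export
detect_candidates <- function(series, cfg = detection_config(), signals = NULL, ...) {
  sig <- signals %||% detection_signals(series, cfg, ...)
  ser <- sig$series
  fs <- ser$sample_rate_hz
  n <- length(ser$t)
  t_end <- if (n) ser$t[n] else 0
  if (t_end < cfg$analysis_end_s && cfg$analysis_start_s > 0)
    warning(sprintf("recording ends at %.1f s, before analysis_end_s = %g; window clipped",
                    t_end, cfg$analysis_end_s))

  v <- as.numeric(sig$velocity)
  above <- !is.na(v) & v > cfg$burst_vel_min_cms
  runs <- find_runs(above)
  runs <- merge_runs(runs, fs, cfg$merge_gap_s)

  imm <- sig$mobility_state == "Immobile"
  imm[is.na(imm)] <- FALSE
  mc_any <- (sig$mc1 %in% TRUE) | (sig$mc2 %in% TRUE)
  ctx <- round(cfg$mc_context_s * fs)
  gap_max <- floor(cfg$pre_gap_max_s * fs + 1e-9)
  need_imm <- ceiling(cfg$pre_immobile_min_s * fs - 1e-9)

  keep <- list()
  for (k in seq_len(nrow(runs))) {
    i0 <- runs$start[k]; i1 <- runs$end[k]
    if (ser$t[i0] < cfg$analysis_start_s || ser$t[i0] > cfg$analysis_end_s) next
    dur <- (i1 - i0 + 1L) / fs
    if (dur > cfg$burst_max_dur_s) next                      # (a)
    peak <- max(v[i0:i1])
    if (peak > cfg$burst_vel_max_cms) next                   # (b)
    pre <- pre_immobile_run(imm, i0, gap_max)                # (c)
    if (pre < need_imm) next
    w0 <- max(1L, i0 - ctx); w1 <- min(n, i1 + ctx)          # (d)
    if (!any(mc_any[w0:w1])) next
    keep[[length(keep) + 1L]] <- data.frame(
      onset_s = ser$t[i0], offset_s = ser$t[i1],
      onset_idx = i0, offset_idx = i1,
      peak_velocity_cms = peak,
      pre_immobile_s = pre / fs,
      mc1_hit = any(sig$mc1[w0:w1] %in% TRUE),
      mc2_hit = any(sig$mc2[w0:w1] %in% TRUE))
  }
  ev <- if (length(keep)) do.call(rbind, keep)
  else data.frame(onset_s = numeric(0), offset_s = numeric(0),
                  onset_idx = integer(0), offset_idx = integer(0),
                  peak_velocity_cms = numeric(0), pre_immobile_s = numeric(0),
                  mc1_hit = logical(0), mc2_hit = logical(0))
  ev$accepted <- rep(NA, nrow(ev))
  ev$rejection_reason <- rep("", nrow(ev))
  ev$pair_id <- rep(NA_integer_, nrow(ev))
  mid <- (cfg$burst_vel_min_cms + cfg$burst_vel_max_cms) / 2
  ev$magnitude_class <- ifelse(ev$peak_velocity_cms >= mid, "large", "modest")
  structure(ev, class = c("myoclonic_events", "data.frame"),
            session_id = ser$session_id, config = cfg, signals = sig)
}

# Maximal TRUE runs of a logical vector, as a data.frame(start, end).
find_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Merge runs whose start-to-previous-end gap is shorter than merge_gap_s.
merge_runs <- function(runs, fs, merge_gap_s) {
  if (nrow(runs) < 2) return(runs)
  gap_lt <- (runs$start[-1] - runs$end[-nrow(runs)] - 1L) / fs < merge_gap_s
  grp <- cumsum(c(TRUE, !gap_lt))
  data.frame(start = tapply(runs$start, grp, min),
             end = tapply(runs$end, grp, max), row.names = NULL)
}

# Length (samples) of the contiguous Immobile run that ends within gap_max
# samples before index i0; 0 if the lag to the nearest Immobile sample
# exceeds gap_max or there is no Immobile sample before i0.
pre_immobile_run <- function(imm, i0, gap_max) {
  j <- i0 - 1L
  lag <- 0L
  while (j >= 1L && !imm[j] && lag < gap_max) { j <- j - 1L; lag <- lag + 1L }
  if (j < 1L || !imm[j]) return(0L)
  len <- 0L
  while (j >= 1L && imm[j]) { j <- j - 1L; len <- len + 1L }
  len
}

#' Classify candidates: reject voluntary movement
#'
#' Automated stand-in for visual confirmation from the video: candidates that
#' plainly reflect voluntary locomotion rather than an involuntary jerk are
#' rejected, with the reason logged so a human can audit every decision. A
#' candidate is rejected iff any of
#'
#' \itemize{
#'   \item \emph{walking-in}: the mobility state was Mobile or HighlyMobile
#'     for more than `walkin_frac` of the `walkin_window_s` seconds before
#'     onset;
#'   \item \emph{sustained locomotion, no spike}: net center displacement
#'     during the burst exceeds `loco_net_disp_cm` while no in-burst sample
#'     exceeds `loco_spike_factor` times the pre-burst velocity maximum
#'     (over `loco_ref_window_s` s);
#'   \item \emph{tracking gap}: the candidate window overlaps an unresolved
#'     (long-gap) missing span, so it cannot be scored.
#' }
#'
#' Movement \emph{after} the event never rejects: a mouse often moves around
#' briefly while recovering from a jerk.
#'
#' @param events Candidates from [detect_candidates()].
#' @param series The same series (only needed when `events` lost its signal
#'   attribute, e.g. after file round-trip).
#' @param cfg A [detection_config()].
#' @return `events` with `accepted` and `rejection_reason` filled.
#' @export
classify_events <- function(events, series = NULL, cfg = attr(events, "config")) {
  sig <- attr(events, "signals")
  if (is.null(sig)) {
    if (is.null(series)) stop("supply 'series' when events carry no signals attribute")
    sig <- detection_signals(series, cfg)
  }
  ser <- sig$series
  fs <- ser$sample_rate_hz
  n <- length(ser$t)
  mobile <- sig$mobility_state %in% c("Mobile", "HighlyMobile")
  v <- as.numeric(sig$velocity)
  ctx <- round(cfg$mc_context_s * fs)
  for (k in seq_len(nrow(events))) {
    i0 <- events$onset_idx[k]; i1 <- events$offset_idx[k]
    reason <- ""
    w0 <- max(1L, i0 - round(cfg$walkin_window_s * fs))
    if (w0 < i0 && mean(mobile[w0:(i0 - 1L)]) > cfg$walkin_frac)
      reason <- "walking-in"
    if (reason == "") {
      net <- sqrt(sum((ser$center[i1, ] - ser$center[i0, ])^2))
      if (net > cfg$loco_net_disp_cm) {
        r0 <- max(1L, i0 - round(cfg$loco_ref_window_s * fs))
        ref <- if (r0 < i0) max(v[r0:(i0 - 1L)], 0, na.rm = TRUE) else 0
        if (!any(v[i0:i1] > cfg$loco_spike_factor * ref, na.rm = TRUE))
          reason <- "sustained locomotion, no spike"
      }
    }
    if (reason == "") {
      g0 <- max(1L, i0 - ctx); g1 <- min(n, i1 + ctx)
      if (any(!sig$valid[g0:g1])) reason <- "tracking gap"
    }
    events$accepted[k] <- reason == ""
    events$rejection_reason[k] <- reason
  }
  events
}

#' Flag consecutive event pairs
#'
#' Adjacent accepted events whose onset gap lies in
#' `[pair_min_gap_s, pair_max_gap_s]` share a `pair_id` (consecutive jerks
#' 1-20 s apart, of which one is often notably larger, are a recognized
#' phenomenon). Pairing is greedy left-to-right and an event belongs to at
#' most one pair. Both members still count as separate events.
#'
#' @param events An event table with `accepted` filled, sorted by onset.
#' @param cfg A [detection_config()].
#' @return `events` with `pair_id` filled.
#' @export
pair_consecutive <- function(events, cfg = attr(events, "config")) {
  acc <- which(events$accepted %in% TRUE)
  events$pair_id[] <- NA_integer_
  pid <- 0L
  k <- 1L
  while (k < length(acc)) {
    gap <- events$onset_s[acc[k + 1L]] - events$onset_s[acc[k]]
    if (gap >= cfg$pair_min_gap_s && gap <= cfg$pair_max_gap_s) {
      pid <- pid + 1L
      events$pair_id[acc[c(k, k + 1L)]] <- pid
      k <- k + 2L
    } else k <- k + 1L
  }
  events
}

#' Per-session event summary
#'
#' Counts accepted events whose onset falls inside the analysis window (the
#' first recording hour is discarded; only the last three hours of a 4-h
#' session are quantified). The headline parameter is the total number of
#' myoclonic events in the observation period.
#'
#' @param events An event table with `accepted` filled.
#' @param cfg A [detection_config()].
#' @param session_id Session identifier for the summary row.
#' @return A one-row data frame: `session_id`, `n_events`, `rate_per_h`,
#'   `n_modest`, `n_large`, `n_paired`, `window_h`.
#' @export
count_events <- function(events, cfg = attr(events, "config"),
                         session_id = attr(events, "session_id")) {
  sel <- (events$accepted %in% TRUE) &
    events$onset_s >= cfg$analysis_start_s & events$onset_s <= cfg$analysis_end_s
  hours <- (cfg$analysis_end_s - cfg$analysis_start_s) / 3600
  data.frame(session_id = session_id %||% NA_character_,
             n_events = sum(sel),
             rate_per_h = sum(sel) / hours,
             n_modest = sum(sel & events$magnitude_class == "modest"),
             n_large = sum(sel & events$magnitude_class == "large"),
             n_paired = sum(sel & !is.na(events$pair_id)),
             window_h = hours)
}

#' Full per-session detection pipeline
#'
#' Convenience wrapper: [detect_candidates()], [classify_events()],
#' [pair_consecutive()].
#'
#' @inheritParams detect_candidates
#' @return A classified, paired `myoclonic_events` table.
#' @export
detect_events <- function(series, cfg = detection_config(), ...) {
  ev <- detect_candidates(series, cfg, ...)
  ev <- classify_events(ev, cfg = cfg)
  pair_consecutive(ev, cfg)
}
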