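#' Simulation configuration
#'
#' Parameters of the ground-truth home-cage simulator: a 4-h overhead
#' recording of a single mouse in a 30 x 30 cm arena that explores early,
#' then mainly sleeps, with involuntary myoclonic jerks injected during sleep
#' as brief velocity bursts, plus grooming bouts, correlated tracking jitter
#' and sporadic tracking dropouts.
#'
#' @param duration_s Session length in seconds (default 4 h).
#' @param sample_rate_hz Sampling rate (default 25 Hz, so 100 samples = 4 s).
#' @param arena_w_cm,arena_h_cm Arena extent in cm.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @param explore_bout_mean_s,sleep_bout_mean_s,groom_bout_mean_s Mean
#'   exponential holding times of the semi-Markov bout chain, s.
#' @param initial_explore_s During the first this-many seconds the chain is
#'   biased toward exploration (animals explore the new cage before settling
#'   to sleep); afterwards it is biased toward sleep.
#' @param jerk_rate_per_h Poisson rate of injected jerks during sleep bouts.
#' @param jerk_peak_cms_range Range the target peak velocity of a jerk is
#'   drawn from (uniform), cm/s; chosen to land inside the ~20-60 cm/s band a
#'   tracked jerk reaches.
#' @param jerk_dur_s_range Range of jerk burst durations (uniform), s.
#' @param pair_prob Probability that a jerk spawns a partner event 1-20 s
#'   later (consecutive-event phenomenon).
#' @param walk_speed_cms_range Locomotion speed range during exploration,
#'   cm/s.
#' @param tracking_noise_sd_cm Stationary SD of the tracking jitter added to
#'   every coordinate, cm. The jitter is a correlated AR(1) process
#'   (`noise_ar1_phi`): raw video-tracking noise is strongly frame-to-frame
#'   correlated, and white noise of the same amplitude would produce
#'   unrealistic velocity floors.
#' @param dropout_prob_per_sample Per-sample probability that the tracker
#'   loses the animal (all fields missing).
#' @param noise_ar1_phi AR(1) coefficient of the tracking jitter.
#' @param recovery_peak_cms_range,recovery_plateau_s_range,recovery_decay_s_range
#'   Slow post-jerk recovery movement: peak speed (cm/s), plateau and decay
#'   durations (s). Mice often move slowly for a moment while recovering
#'   from a jerk.
#' @param jerk_min_sep_s Minimum separation enforced between base jerks so
#'   each emerges from re-established immobility, s.
#' @param jerk_margin_start_s,jerk_margin_end_s Margins from the sleep-bout
#'   edges inside which jerks may be placed, s.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(duration_s = 14400, sample_rate_hz = 25,
                              arena_w_cm = 30, arena_h_cm = 30,
                              seed = 1L,
                              explore_bout_mean_s = 60,
                              sleep_bout_mean_s = 600,
                              groom_bout_mean_s = 30,
                              initial_explore_s = 3600,
                              jerk_rate_per_h = 4,
                              jerk_peak_cms_range = c(25, 55),
                              jerk_dur_s_range = c(0.2, 0.8),
                              pair_prob = 0.15,
                              walk_speed_cms_range = c(5, 15),
                              tracking_noise_sd_cm = 0.05,
                              dropout_prob_per_sample = 0.001,
                              noise_ar1_phi = 0.9,
                              recovery_peak_cms_range = c(3, 5),
                              recovery_plateau_s_range = c(0.3, 0.8),
                              recovery_decay_s_range = c(0.3, 1.0),
                              jerk_min_sep_s = 30,
                              jerk_margin_start_s = 15,
                              jerk_margin_end_s = 3) {
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  chk <- function(cond, msg) if (!cond) stop("invalid simulation config: ", msg)
  chk(cfg$duration_s > 0, "duration_s must be positive")
  chk(cfg$sample_rate_hz > 0, "sample_rate_hz must be positive")
  chk(cfg$jerk_rate_per_h >= 0, "jerk_rate_per_h must be >= 0")
  chk(cfg$pair_prob >= 0 && cfg$pair_prob <= 1, "pair_prob must be in [0, 1]")
  chk(all(diff(cfg$jerk_peak_cms_range) > 0), "jerk_peak_cms_range must be increasing")
  chk(all(diff(cfg$jerk_dur_s_range) > 0), "jerk_dur_s_range must be increasing")
  chk(all(diff(cfg$walk_speed_cms_range) > 0), "walk_speed_cms_range must be increasing")
  chk(cfg$jerk_dur_s_range[2] + cfg$jerk_margin_start_s + cfg$jerk_margin_end_s < 30,
      "jerk duration plus placement margins exceed the minimum sleep bout; no jerk can be placed")
  chk(cfg$dropout_prob_per_sample >= 0 && cfg$dropout_prob_per_sample < 1,
      "dropout_prob_per_sample must be in [0, 1)")
  cfg
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  for (f in names(x)) cat(sprintf("  %-26s %s\n", f, paste(format(x[[f]]), collapse = " ")))
  invisible(x)
}

unit_vec <- function(angle) cbind(cos(angle), sin(angle))

#' Simulate a home-cage session with ground truth
#'
#' Generates a [tracking_series()] plus the ground-truth annotation used as
#' the acceptance oracle. Behavior alternates bouts of exploration (smooth
#' correlated random walk, stretched posture), sleep (stationary curled
#' posture, sub-threshold jitter) and grooming (in-place oscillation). Jerks
#' are injected at Poisson times within established sleep as out-and-back
#' half-sine displacement pulses whose peak velocity hits a sampled target in
#' the 20-60 cm/s band, followed by brief slow recovery movement; a jerk may
#' spawn a partner event 1-20 s later. Correlated Gaussian tracking jitter
#' and random dropouts are applied last.
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements `series` (a `tracking_series`) and `truth`
#'   (class `ground_truth`: data frames `jerks` with `time_s`, `peak_cms`,
#'   `duration_s`, `pair_id`, and `bouts` with `start_s`, `end_s`, `label`).
#' @export
simulate_session <- function(cfg = simulation_config()) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(cfg$seed))

  fs <- cfg$sample_rate_hz
  n <- as.integer(round(cfg$duration_s * fs)) + 1L
  t <- (seq_len(n) - 1L) / fs
  W <- cfg$arena_w_cm; H <- cfg$arena_h_cm

  bouts <- sim_bouts(cfg)
  st <- sim_baseline(cfg, bouts, n, t)
  inj <- sim_inject_jerks(cfg, bouts, st, n, t)
  st <- inj$st
  jerks <- inj$jerks

  # posture-consistent body points: nose/tail at half body length from the
  # center, split by the bend angle around the heading
  len_cm <- 3.5 + 3.5 * st$elong / 100
  half_b <- st$beta * pi / 360         # beta/2 in radians
  nose <- st$center + (len_cm / 2) * unit_vec(st$theta + half_b)
  tail <- st$center - (len_cm / 2) * unit_vec(st$theta - half_b)
  nose <- nose + st$nose_sway * unit_vec(st$theta + pi / 2)
  # the stored body angle is the geometric deviation from collinearity of the
  # stored points (head sway included), so series and shape agree
  st$beta <- deviation_deg_rows(st$center, nose, tail)

  ar1 <- function(n, sd, phi) {
    if (sd <= 0) return(numeric(n))
    e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
    stats::filter(e, phi, method = "recursive") |> as.numeric()
  }
  jit <- function(m) m + cbind(ar1(n, cfg$tracking_noise_sd_cm, cfg$noise_ar1_phi),
                               ar1(n, cfg$tracking_noise_sd_cm, cfg$noise_ar1_phi))
  center <- jit(st$center); nose <- jit(nose); tail <- jit(tail)
  elong <- pmin(100, pmax(0, st$elong + ar1(n, 0.4, cfg$noise_ar1_phi)))
  beta <- pmin(180, pmax(0, st$beta + ar1(n, 0.8, cfg$noise_ar1_phi)))

  clamp_xy <- function(m, pad = 0.05)
    cbind(pmin(W - pad, pmax(pad, m[, 1])), pmin(H - pad, pmax(pad, m[, 2])))
  center <- clamp_xy(center); nose <- clamp_xy(nose); tail <- clamp_xy(tail)

  missing <- stats::runif(n) < cfg$dropout_prob_per_sample
  if (any(missing)) {
    center[missing, ] <- NA_real_
    nose[missing, ] <- NA_real_
    tail[missing, ] <- NA_real_
    elong[missing] <- NA_real_
    beta[missing] <- NA_real_
  }

  series <- tracking_series(
    session_id = sprintf("sim-seed%d", as.integer(cfg$seed)),
    sample_rate_hz = fs, t = t,
    center = center, nose = nose, tail = tail,
    elongation_pct = elong, body_angle_deg = beta,
    missing = missing, arena_w_cm = W, arena_h_cm = H)
  truth <- structure(list(jerks = jerks, bouts = bouts), class = "ground_truth")
  list(series = series, truth = truth)
}

# Semi-Markov bout chain: exponential holding times, no self-transitions,
# explore-biased during the initial phase, sleep-biased afterwards.
sim_bouts <- function(cfg) {
  labels <- c("explore", "sleep", "groom")
  means <- c(explore = cfg$explore_bout_mean_s, sleep = cfg$sleep_bout_mean_s,
             groom = cfg$groom_bout_mean_s)
  probs_early <- c(explore = 0.65, sleep = 0.10, groom = 0.25)
  probs_late <- c(explore = 0.15, sleep = 0.70, groom = 0.15)
  out <- list()
  t0 <- 0
  cur <- "explore"
  while (t0 < cfg$duration_s) {
    dur <- max(5, stats::rexp(1, 1 / means[[cur]]))
    if (cur == "sleep") dur <- max(30, dur)
    t1 <- min(cfg$duration_s, t0 + dur)
    out[[length(out) + 1L]] <- data.frame(start_s = t0, end_s = t1, label = cur)
    t0 <- t1
    p <- if (t0 < cfg$initial_explore_s) probs_early else probs_late
    p[cur] <- 0
    cur <- sample(labels, 1, prob = p / sum(p))
  }
  do.call(rbind, out)
}

# Noise-free baseline trajectories: center path, heading, elongation, bend
# angle, nose sway, all per sample, by walking the bout schedule.
sim_baseline <- function(cfg, bouts, n, t) {
  fs <- cfg$sample_rate_hz
  W <- cfg$arena_w_cm; H <- cfg$arena_h_cm
  cx <- numeric(n); cy <- numeric(n)
  theta <- numeric(n); elong <- numeric(n); beta <- numeric(n)
  sway <- numeric(n)
  pos <- c(W / 2 + stats::runif(1, -5, 5), H / 2 + stats::runif(1, -5, 5))
  head <- stats::runif(1, 0, 2 * pi)
  e_cur <- 90; b_cur <- 10
  # keep the center far enough from the wall that nose and tail (half a body
  # length away) stay inside the arena
  margin <- 4.2
  for (k in seq_len(nrow(bouts))) {
    i0 <- as.integer(floor(bouts$start_s[k] * fs)) + 1L
    i1 <- if (k == nrow(bouts)) n else as.integer(floor(bouts$end_s[k] * fs))
    if (i1 < i0) next
    idx <- i0:i1
    m <- length(idx)
    tt <- t[idx] - t[idx[1]]
    lab <- bouts$label[k]
    if (lab == "explore") {
      spd_mu <- mean(cfg$walk_speed_cms_range)
      spd <- spd_mu
      e_tgt <- stats::runif(1, 85, 97)
      steer <- margin + 1.5
      wrap <- function(a) ((a + pi) %% (2 * pi)) - pi
      for (j in seq_len(m)) {
        # smooth steering: turn toward the arena center near walls (an
        # instantaneous bounce would rotate the body within one sample)
        if (pos[1] < steer || pos[1] > W - steer ||
            pos[2] < steer || pos[2] > H - steer) {
          d <- wrap(atan2(H / 2 - pos[2], W / 2 - pos[1]) - head)
          head <- head + sign(d) * min(abs(d), 0.22) + stats::rnorm(1, 0, 0.05)
        } else head <- head + stats::rnorm(1, 0, 0.25)
        spd <- spd + 0.08 * (spd_mu - spd) + stats::rnorm(1, 0, 0.5)
        spd <- min(cfg$walk_speed_cms_range[2], max(cfg$walk_speed_cms_range[1], spd))
        pos <- pos + (spd / fs) * c(cos(head), sin(head))
        pos <- c(min(W - margin, max(margin, pos[1])),
                 min(H - margin, max(margin, pos[2])))
        cx[idx[j]] <- pos[1]; cy[idx[j]] <- pos[2]; theta[idx[j]] <- head
      }
      e_cur <- e_tgt
      elong[idx] <- e_tgt + 2 * sin(2 * pi * 0.2 * tt)
      # a walking mouse keeps a fairly straight body; strong bends belong to
      # grooming postures
      b_cur <- stats::runif(1, 2, 8)
      beta[idx] <- pmax(0, b_cur + 3 * sin(2 * pi * 0.8 * tt))
      sway[idx] <- 0.35 * sin(2 * pi * 3 * tt)
    } else if (lab == "sleep") {
      cx[idx] <- pos[1]; cy[idx] <- pos[2]; theta[idx] <- head
      e_cur <- stats::runif(1, 55, 68)
      elong[idx] <- e_cur + 1.5 * sin(2 * pi * 1.5 * tt)
      b_cur <- stats::runif(1, 3, 13)
      beta[idx] <- pmax(0, b_cur + 1.5 * sin(2 * pi * 0.3 * tt))
      sway[idx] <- 0
    } else { # groom: in-place rocking and head bobbing
      rock_dir <- head + pi / 2
      amp <- stats::runif(1, 0.3, 0.6)
      osc <- amp * sin(2 * pi * 2.5 * tt)
      cx[idx] <- pos[1] + osc * cos(rock_dir)
      cy[idx] <- pos[2] + osc * sin(rock_dir)
      theta[idx] <- head
      e_cur <- stats::runif(1, 58, 68)
      elong[idx] <- e_cur + 7 * sin(2 * pi * 2.5 * tt)
      b_cur <- stats::runif(1, 14, 26)
      beta[idx] <- pmax(0, b_cur + 8 * sin(2 * pi * 2.5 * tt))
      sway[idx] <- 0.55 * sin(2 * pi * 2.8 * tt)
    }
  }
  list(center = cbind(cx, cy), theta = theta,
       elong = pmin(100, pmax(0, elong)), beta = pmin(180, beta), nose_sway = sway)
}

# Draw jerk times inside established sleep, synthesize their displacement
# pulses into the baseline, and return both the ground-truth jerk table and
# the updated baseline.
sim_inject_jerks <- function(cfg, bouts, st, n, t) {
  fs <- cfg$sample_rate_hz
  jerk_rows <- list()
  pair_id <- 0L
  sleep <- bouts[bouts$label == "sleep", , drop = FALSE]
  for (k in seq_len(nrow(sleep))) {
    lo <- sleep$start_s[k] + cfg$jerk_margin_start_s
    hi <- sleep$end_s[k] - cfg$jerk_margin_end_s - cfg$jerk_dur_s_range[2] -
      max(cfg$recovery_plateau_s_range) - max(cfg$recovery_decay_s_range)
    if (hi <= lo) next
    n_j <- stats::rpois(1, cfg$jerk_rate_per_h * (hi - lo) / 3600)
    if (n_j == 0) next
    times <- sort(stats::runif(n_j, lo, hi))
    kept <- numeric(0)
    for (tm in times)
      if (!length(kept) || tm - kept[length(kept)] >= cfg$jerk_min_sep_s)
        kept <- c(kept, tm)
    for (tm in kept) {
      base <- data.frame(time_s = tm,
                         peak_cms = stats::runif(1, cfg$jerk_peak_cms_range[1],
                                                 cfg$jerk_peak_cms_range[2]),
                         duration_s = stats::runif(1, cfg$jerk_dur_s_range[1],
                                                   cfg$jerk_dur_s_range[2]),
                         pair_id = NA_integer_)
      rows <- base
      if (stats::runif(1) < cfg$pair_prob) {
        gap <- stats::runif(1, 1, 20)
        tp <- tm + gap
        nxt <- kept[kept > tm]
        room_next <- !length(nxt) || (nxt[1] - tp > cfg$jerk_dur_s_range[2] + 3)
        if (tp < hi && room_next) {
          pair_id <- pair_id + 1L
          rows$pair_id <- pair_id
          rows <- rbind(rows, data.frame(
            time_s = tp,
            peak_cms = stats::runif(1, cfg$jerk_peak_cms_range[1],
                                    cfg$jerk_peak_cms_range[2]),
            duration_s = stats::runif(1, cfg$jerk_dur_s_range[1],
                                      cfg$jerk_dur_s_range[2]),
            pair_id = pair_id))
        }
      }
      jerk_rows[[length(jerk_rows) + 1L]] <- rows
    }
  }
  jerks <- if (length(jerk_rows)) do.call(rbind, jerk_rows)
  else data.frame(time_s = numeric(0), peak_cms = numeric(0),
                  duration_s = numeric(0), pair_id = integer(0))
  jerks <- jerks[order(jerks$time_s), , drop = FALSE]
  row.names(jerks) <- NULL

  W <- cfg$arena_w_cm; H <- cfg$arena_h_cm
  for (r in seq_len(nrow(jerks))) {
    tm <- jerks$time_s[r]; d <- jerks$duration_s[r]; vp <- jerks$peak_cms[r]
    i0 <- as.integer(round(tm * fs)) + 1L
    pos0 <- st$center[i0, ]
    to_center <- atan2(H / 2 - pos0[2], W / 2 - pos0[1])
    a1 <- to_center + stats::runif(1, -pi / 4, pi / 4)
    u1 <- c(cos(a1), sin(a1))
    rot <- stats::runif(1, pi / 3, 2 * pi / 3)
    sgn <- sample(c(-1, 1), 1)
    rec_total <- 5 * (d / 4 + max(cfg$recovery_plateau_s_range) +
                        max(cfg$recovery_decay_s_range) / 2)
    u2 <- NULL
    for (s2 in c(sgn, -sgn)) {  # pick a recovery heading that stays in-arena
      cand <- c(cos(a1 + s2 * rot), sin(a1 + s2 * rot))
      endp <- pos0 + rec_total * cand
      if (all(endp > 1) && endp[1] < W - 1 && endp[2] < H - 1) { u2 <- cand; break }
    }
    if (is.null(u2)) u2 <- u1
    # out-and-back half-sine-squared pulse: peak speed vp at t = d/4 and 3d/4
    E <- vp * d / pi
    n_b <- as.integer(ceiling(d * fs))
    tau_b <- (seq_len(n_b)) / fs
    tau_b <- tau_b[tau_b <= d]
    bump <- E * sin(pi * tau_b / d)^2
    # slow recovery: ramp during the pulse's second half, plateau, decay
    vr <- stats::runif(1, cfg$recovery_peak_cms_range[1], cfg$recovery_peak_cms_range[2])
    t_pl <- stats::runif(1, cfg$recovery_plateau_s_range[1], cfg$recovery_plateau_s_range[2])
    t_dc <- stats::runif(1, cfg$recovery_decay_s_range[1], cfg$recovery_decay_s_range[2])
    rec_dur <- d / 2 + t_pl + t_dc
    n_r <- as.integer(ceiling(rec_dur * fs))
    tau_r <- (seq_len(n_r)) / fs
    rec_speed <- ifelse(tau_r <= d / 2, vr * tau_r / (d / 2),
                 ifelse(tau_r <= d / 2 + t_pl, vr,
                        vr * pmax(0, 1 - (tau_r - d / 2 - t_pl) / t_dc)))
    rec <- cumsum(rec_speed) / fs
    len <- max(length(bump), length(rec))
    off <- matrix(0, len, 2)
    off[seq_along(bump), ] <- off[seq_along(bump), ] + outer(bump, u1)
    off[seq_along(rec), ] <- off[seq_along(rec), ] + outer(rec, u2)
    i_span <- i0 + seq_len(len)
    i_span <- i_span[i_span <= n]
    st$center[i_span, ] <- st$center[i_span, ] + off[seq_along(i_span), ]
    # the animal ends displaced by the recovery drift; shift the rest of the
    # sleep bout so it keeps sleeping at the new spot, then fade the shift
    # out over a few seconds of the following bout so the baseline rejoins
    # without a velocity jump
    if (length(i_span) && max(i_span) < n) {
      drift <- rec[length(rec)] * u2
      rest <- (max(i_span) + 1L):n
      bout_end_t <- sleep_bout_end(bouts, tm)
      rest <- rest[t[rest] <= bout_end_t]
      if (length(rest))
        st$center[rest, ] <- st$center[rest, ] + matrix(drift, length(rest), 2, byrow = TRUE)
      fade_n <- as.integer(round(4 * fs))
      last_shifted <- if (length(rest)) max(rest) else max(i_span)
      after <- (last_shifted + 1L):n
      after <- after[after <= last_shifted + fade_n & after <= n]
      if (length(after)) {
        w <- 1 - seq_along(after) / (length(after) + 1L)
        st$center[after, ] <- st$center[after, ] + outer(w, drift)
      }
    }
    # brief postural stretch during the pulse
    i_b <- i0 + seq_along(bump)
    i_b <- i_b[i_b <= n]
    st$elong[i_b] <- pmin(97, st$elong[i_b] + 15 * sin(pi * tau_b[seq_along(i_b)] / d)^2)
  }
  st$center[, 1] <- pmin(W - 0.1, pmax(0.1, st$center[, 1]))
  st$center[, 2] <- pmin(H - 0.1, pmax(0.1, st$center[, 2]))
  list(jerks = jerks, st = st)
}

# row-wise deviation-from-collinearity angle (degrees) at the center
deviation_deg_rows <- function(center, nose, tail) {
  a <- nose - center; b <- tail - center
  na <- sqrt(rowSums(a^2)); nb <- sqrt(rowSums(b^2))
  cosang <- rowSums(a * b) / pmax(na * nb, 1e-12)
  180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

sleep_bout_end <- function(bouts, time_s) {
  hit <- bouts$label == "sleep" & bouts$start_s <= time_s & bouts$end_s > time_s
  if (any(hit)) bouts$end_s[which(hit)[1]] else time_s
}

#' Read/write ground truth JSON
#'
#' @param truth A `ground_truth` object from [simulate_session()].
#' @param path JSON file path.
#' @return `path` invisibly, or the `ground_truth` object.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(jerks = truth$jerks, bouts = truth$bouts),
                       path, auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  jerks <- as.data.frame(x$jerks)
  if (!nrow(jerks)) jerks <- data.frame(time_s = numeric(0), peak_cms = numeric(0),
                                        duration_s = numeric(0), pair_id = integer(0))
  structure(list(jerks = jerks, bouts = as.data.frame(x$bouts)),
            class = "ground_truth")
}
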