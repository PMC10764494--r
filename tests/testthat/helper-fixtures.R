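# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures on disk.

# A stationary series with straight posture, convenient for hand-built cases.
make_still_series <- function(n, fs = 25, at = c(15, 15), elong = 60, angle = 5,
                              session_id = "still") {
  tracking_series(
    session_id = session_id, sample_rate_hz = fs, t = (seq_len(n) - 1) / fs,
    center = matrix(rep(at, each = n), n, 2),
    nose = matrix(rep(at + c(2.5, 0), each = n), n, 2),
    tail = matrix(rep(at - c(2.5, 0), each = n), n, 2),
    elongation_pct = rep(elong, n), body_angle_deg = rep(angle, n))
}

# Build a series whose center follows a prescribed per-sample speed profile
# (cm/s) along +x, folding back inside the arena; nose/tail ride along.
make_speed_series <- function(speed_cms, fs = 25, start = c(4, 15),
                              elong = 60, angle = 5, session_id = "profile") {
  n <- length(speed_cms)
  step <- speed_cms / fs
  # zig-zag in x to stay inside a 30 cm arena regardless of path length
  xraw <- start[1] + cumsum(c(0, step[-1]))
  span <- 22
  fold <- abs((xraw - 4) %% (2 * span) - span) + 4
  center <- cbind(fold, rep(start[2], n))
  if (length(elong) == 1) elong <- rep(elong, n)
  if (length(angle) == 1) angle <- rep(angle, n)
  tracking_series(
    session_id = session_id, sample_rate_hz = fs, t = (seq_len(n) - 1) / fs,
    center = center,
    nose = cbind(pmin(29.9, center[, 1] + 2.5), center[, 2]),
    tail = cbind(pmax(0.1, center[, 1] - 2.5), center[, 2]),
    elongation_pct = elong, body_angle_deg = angle)
}

# A randomized session for oracle-equivalence testing: alternating rest,
# walking and velocity spikes of assorted peaks/durations, occasional
# dropouts -- designed to exercise every candidate criterion branch.
random_series <- function(seed, n_max = 5000, fs = 25) {
  set.seed(seed)
  n <- sample(1500:n_max, 1)
  speed <- numeric(n)
  i <- 1
  while (i <= n) {
    what <- sample(c("rest", "walk", "spike"), 1, prob = c(0.55, 0.2, 0.25))
    if (what == "rest") {
      len <- sample(round(fs * c(4, 40)), 1)
      len <- min(len, n - i + 1)
      speed[i:(i + len - 1)] <- abs(rnorm(len, 0, 0.3))
      i <- i + len
    } else if (what == "walk") {
      len <- sample(round(fs * c(2, 12)), 1)
      len <- min(len, n - i + 1)
      speed[i:(i + len - 1)] <- pmax(0, rnorm(len, runif(1, 4, 14), 1))
      i <- i + len
    } else {
      dur <- runif(1, 0.1, 2.2)
      len <- max(2L, round(dur * fs))
      len <- min(len, n - i + 1)
      peak <- runif(1, 15, 80)
      speed[i:(i + len - 1)] <- peak * sin(pi * seq_len(len) / (len + 1))
      i <- i + len
      # occasional twin spike close enough to merge
      if (runif(1) < 0.3 && i + 10 < n) {
        gap <- sample(2:20, 1)
        len2 <- min(sample(3:10, 1), n - i - gap)
        if (len2 >= 2) {
          peak2 <- runif(1, 15, 70)
          speed[(i + gap):(i + gap + len2 - 1)] <-
            peak2 * sin(pi * seq_len(len2) / (len2 + 1))
          i <- i + gap + len2
        }
      }
    }
  }
  ser <- make_speed_series(speed, fs = fs,
                           elong = pmin(100, pmax(0, 60 + cumsum(rnorm(n, 0, 0.5)) * 0.2)),
                           angle = pmin(60, pmax(0, 10 + cumsum(rnorm(n, 0, 0.5)) * 0.2)),
                           session_id = sprintf("random-%d", seed))
  drop <- runif(n) < 0.002
  if (any(drop)) {
    ser$center[drop, ] <- NA_real_
    ser$nose[drop, ] <- NA_real_
    ser$tail[drop, ] <- NA_real_
    ser$elongation_pct[drop] <- NA_real_
    ser$body_angle_deg[drop] <- NA_real_
    ser$missing <- drop
  }
  ser
}

# Inject a velocity burst (half-sine speed bump plus a short slow-recovery
# tail) into a series by displacing all three body points along +x.
inject_test_burst <- function(ser, at_s, peak, dur_s = 0.4, recovery = TRUE) {
  fs <- ser$sample_rate_hz
  len <- max(2L, round(dur_s * fs))
  sp <- peak * sin(pi * seq_len(len) / (len + 1))
  if (recovery) sp <- c(sp, rep(3.5, 8), seq(3.5, 0, length.out = 5))
  offs <- cumsum(sp) / fs
  i0 <- as.integer(round(at_s * fs)) + 1L
  n <- length(ser$t)
  idx <- i0 + seq_along(offs)
  idx_ok <- idx[idx <= n]
  for (f in c("center", "nose", "tail")) {
    ser[[f]][idx_ok, 1] <- ser[[f]][idx_ok, 1] + offs[seq_along(idx_ok)]
    later <- idx_ok[length(idx_ok)]
    if (later < n)
      ser[[f]][(later + 1L):n, 1] <- ser[[f]][(later + 1L):n, 1] + offs[length(offs)]
  }
  ser
}

# Detection configuration whose analysis window spans a whole short series.
full_window_cfg <- function(..., end_s = 14400) {
  detection_config(analysis_start_s = 0, analysis_end_s = end_s, ...)
}
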