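test_that("a jerk emerging from long immobility yields exactly one candidate", {
  ser <- inject_test_burst(make_still_series(3000), at_s = 60, peak = 50, dur_s = 0.4)
  cfg <- full_window_cfg()
  ev <- detect_candidates(ser, cfg)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$onset_s - 60), 0.5)
  expect_gte(ev$peak_velocity_cms, 20)
  expect_lte(ev$peak_velocity_cms, 60)
  expect_gte(ev$pre_immobile_s, 10)
  expect_true(ev$mc1_hit || ev$mc2_hit)
  expect_identical(ev$magnitude_class, "large")

  # classification accepts it: no walking-in, no gap
  ev <- classify_events(ev, cfg = cfg)
  expect_true(ev$accepted)
  expect_identical(ev$rejection_reason, "")
})

test_that("bursts outside the 20-60 cm/s band are not candidates", {
  cfg <- full_window_cfg()
  hot <- inject_test_burst(make_still_series(3000), at_s = 60, peak = 80)
  expect_equal(nrow(detect_candidates(hot, cfg)), 0L)
  cold <- inject_test_burst(make_still_series(3000), at_s = 60, peak = 15)
  expect_equal(nrow(detect_candidates(cold, cfg)), 0L)
})

test_that("a quiet session yields no candidates", {
  sim <- simulate_session(simulation_config(duration_s = 300, seed = 2,
                                            initial_explore_s = 60,
                                            jerk_rate_per_h = 0))
  ev <- detect_candidates(sim$series, full_window_cfg(end_s = 300))
  expect_equal(nrow(ev), 0L)
})

test_that("runs closer than the merge gap collapse into one candidate", {
  ser <- make_still_series(3000)
  ser <- inject_test_burst(ser, at_s = 60, peak = 35, dur_s = 0.3, recovery = FALSE)
  ser <- inject_test_burst(ser, at_s = 60.8, peak = 45, dur_s = 0.3)
  ev <- detect_candidates(ser, full_window_cfg())
  expect_equal(nrow(ev), 1L)
  expect_gt(ev$peak_velocity_cms, 40)
  expect_lte(ev$offset_s - ev$onset_s, 1.5)
})

test_that("a burst without the required preceding immobility is rejected at scan time", {
  # immobile for only 5 s before the burst: walking until t = 55
  walk <- c(rep(10, 55 * 25), rep(0, 5 * 25), rep(0, 1500))
  ser <- inject_test_burst(make_speed_series(walk), at_s = 60, peak = 40)
  expect_equal(nrow(detect_candidates(ser, full_window_cfg())), 0L)
})

test_that("walking-in candidates are rejected with the stated reason", {
  # disable the immobility precondition so a mid-locomotion spike becomes a
  # candidate, then let the classifier catch it
  cfg <- full_window_cfg(pre_immobile_min_s = 0)
  walk <- c(rep(0, 500), rep(12, 500), 30, 35, 30, rep(12, 500))
  ser <- make_speed_series(walk)
  ev <- detect_candidates(ser, cfg)
  expect_gte(nrow(ev), 1L)
  ev <- classify_events(ev, cfg = cfg)
  expect_true(any(ev$rejection_reason == "walking-in"))
  expect_false(any(ev$accepted[ev$rejection_reason == "walking-in"]))
})

test_that("post-event locomotion does not reject an event", {
  ser <- make_still_series(4000)
  ser <- inject_test_burst(ser, at_s = 60, peak = 40)
  # 5 s of walking shortly after the event, then quiet again
  fs <- 25
  i0 <- 63 * fs
  walkoff <- cumsum(rep(8 / fs, 5 * fs))
  idx <- i0 + seq_along(walkoff)
  for (f in c("center", "nose", "tail")) {
    ser[[f]][idx, 2] <- ser[[f]][idx, 2] + walkoff
    ser[[f]][(max(idx) + 1):length(ser$t), 2] <-
      ser[[f]][(max(idx) + 1):length(ser$t), 2] + max(walkoff)
  }
  ev <- detect_events(ser, full_window_cfg())
  expect_equal(nrow(ev), 1L)
  expect_true(ev$accepted)
})

test_that("candidates overlapping an unresolved tracking gap are rejected", {
  ser <- inject_test_burst(make_still_series(3000), at_s = 60, peak = 40)
  gap <- (60.2 * 25):(62.2 * 25)  # 2 s dropout right after onset
  ser$missing[gap] <- TRUE
  ser$center[gap, ] <- NA; ser$nose[gap, ] <- NA; ser$tail[gap, ] <- NA
  ser$elongation_pct[gap] <- NA; ser$body_angle_deg[gap] <- NA
  ev <- detect_events(ser, full_window_cfg())
  if (nrow(ev)) {
    expect_false(any(ev$accepted))
    expect_true(all(ev$rejection_reason == "tracking gap"))
  } else succeed("burst destroyed by the gap itself")
})

test_that("greedy pairing links consecutive events 1-20 s apart exactly once", {
  cfg <- detection_config()
  mk <- function(onsets) {
    ev <- data.frame(onset_s = onsets, offset_s = onsets + 0.4,
                     onset_idx = NA_integer_, offset_idx = NA_integer_,
                     peak_velocity_cms = 40, pre_immobile_s = 30,
                     mc1_hit = FALSE, mc2_hit = TRUE, accepted = TRUE,
                     rejection_reason = "", pair_id = NA_integer_,
                     magnitude_class = "large")
    structure(ev, class = c("myoclonic_events", "data.frame"))
  }
  p1 <- pair_consecutive(mk(c(100, 110)), cfg)
  expect_equal(p1$pair_id, c(1L, 1L))
  p2 <- pair_consecutive(mk(c(100, 130)), cfg)
  expect_true(all(is.na(p2$pair_id)))
  p3 <- pair_consecutive(mk(c(100, 105, 112)), cfg)
  expect_equal(p3$pair_id, c(1L, 1L, NA))
  # sub-1-s gaps never pair
  p4 <- pair_consecutive(mk(c(100, 100.5)), cfg)
  expect_true(all(is.na(p4$pair_id)))
  # rejected events are invisible to pairing
  ev5 <- mk(c(100, 110, 115))
  ev5$accepted[2] <- FALSE
  p5 <- pair_consecutive(ev5, cfg)
  expect_equal(p5$pair_id, c(1L, NA, 1L))
})

test_that("count_events applies the last-three-hours analysis window", {
  cfg <- detection_config()
  mk <- function(onsets) {
    n <- length(onsets)
    structure(data.frame(onset_s = onsets, offset_s = onsets + 0.4,
                         peak_velocity_cms = rep(30, n), pre_immobile_s = rep(30, n),
                         mc1_hit = rep(FALSE, n), mc2_hit = rep(TRUE, n),
                         accepted = rep(TRUE, n), rejection_reason = rep("", n),
                         pair_id = rep(NA_integer_, n),
                         magnitude_class = rep("modest", n)),
              class = c("myoclonic_events", "data.frame"))
  }
  expect_equal(count_events(mk(1800), cfg, "s")$n_events, 0L)
  cnt <- count_events(mk(c(4000, 8000, 14000)), cfg, "s")
  expect_equal(cnt$n_events, 3L)
  expect_equal(cnt$rate_per_h, 1.0)
  expect_equal(count_events(mk(numeric(0)), cfg, "s")$n_events, 0L)
})

test_that("detection is deterministic and matches the brute-force oracle", {
  cfg <- full_window_cfg()
  for (seed in c(101, 202, 303, 404)) {
    ser <- random_series(seed, n_max = 3000)
    expect_oracle_equal(ser, cfg)
  }
  ser <- random_series(55, n_max = 2500)
  e1 <- detect_events(ser, cfg)
  e2 <- detect_events(ser, cfg)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
})

test_that("widening the burst band or shortening pre-immobility never loses candidates", {
  cfg <- full_window_cfg()
  wide <- full_window_cfg(burst_vel_min_cms = 15, burst_vel_max_cms = 80,
                          pre_immobile_min_s = 5)
  for (seed in c(61, 62, 63)) {
    ser <- random_series(seed, n_max = 2500)
    n_base <- nrow(detect_candidates(ser, cfg))
    n_wide <- nrow(detect_candidates(ser, wide))
    expect_gte(n_wide, n_base)
  }
})

test_that("a short recording clips the default analysis window with a warning", {
  ser <- inject_test_burst(make_still_series(2000), at_s = 40, peak = 40)
  expect_warning(detect_candidates(ser, detection_config()), "clipped")
})
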