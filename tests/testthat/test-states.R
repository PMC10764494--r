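sig25 <- function(v) track_signal(v, "cm/s", 25)

test_that("movement hysteresis steps through start/stop thresholds", {
  expect_equal(movement_state(sig25(rep(0, 20)), 3.20, 2.25), rep(FALSE, 20))
  expect_equal(movement_state(sig25(rep(10, 20)), 3.20, 2.25), rep(TRUE, 20))
  expect_equal(movement_state(sig25(c(1, 4, 3, 2, 1)), 3.20, 2.25),
               c(FALSE, TRUE, TRUE, FALSE, FALSE))
  # NA holds the previous state
  expect_equal(movement_state(sig25(c(5, NA, NA, 1, NA)), 3.20, 2.25),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_error(movement_state(sig25(1:3), 2, 2), "below")
})

test_that("hysteresis is causal: the state at i depends only on samples <= i", {
  set.seed(11)
  for (rep in 1:20) {
    v <- abs(rnorm(300, 2.5, 1.5))
    full <- movement_state(sig25(v), 3.2, 2.25)
    cut <- sample(2:299, 1)
    prefix <- movement_state(sig25(v[1:cut]), 3.2, 2.25)
    expect_identical(full[1:cut], prefix)
  }
})

test_that("raising both thresholds never increases time spent Moving", {
  set.seed(12)
  for (rep in 1:20) {
    v <- abs(rnorm(400, 3, 2))
    lo <- movement_state(sig25(v), 3.2, 2.25)
    hi <- movement_state(sig25(v), 4.2, 3.25)
    expect_lte(sum(hi), sum(lo))
    # and pointwise: wherever the stricter automaton moves, the looser does
    expect_true(all(lo[hi]))
  }
})

test_that("mobility surrogate matches its defining formula", {
  cfg <- detection_config()
  still <- make_still_series(50)
  expect_equal(as.numeric(mobility_raw(still, cfg)), rep(0, 50))

  # all three points displacing one body length per sample, fixed posture
  n <- 20
  stepper <- tracking_series("step", 25, (0:(n - 1)) / 25,
    center = cbind(seq(1, by = 7, length.out = n) %% 28 + 1, 15),
    nose = cbind(seq(1, by = 7, length.out = n) %% 28 + 1, 14),
    tail = cbind(seq(1, by = 7, length.out = n) %% 28 + 1, 16),
    elongation_pct = rep(70, n), body_angle_deg = rep(5, n),
    arena_w_cm = 30, arena_h_cm = 30)
  mob <- as.numeric(mobility_raw(stepper, cfg))
  # w1+w2+w3 = 0.9, each displacement d_p = 1 body length (wrap steps excluded)
  steps_ok <- which(abs(diff(stepper$center[, 1]) - 7) < 1e-9) + 1L
  expect_equal(mob[steps_ok], rep(90, length(steps_ok)), tolerance = 1e-9)

  ser <- random_series(21, n_max = 1500)
  ser <- interpolate_gaps(ser, 1)
  got <- as.numeric(mobility_raw(ser, cfg))
  d <- function(m) c(0, sqrt(diff(m[, 1])^2 + diff(m[, 2])^2))
  want <- 100 * pmin(1, 0.3 * d(ser$center) / 7 + 0.3 * d(ser$nose) / 7 +
                        0.3 * d(ser$tail) / 7 +
                        0.1 * c(0, abs(diff(ser$elongation_pct))) / 100)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("mobility state thresholds the averaged trace into three exclusive levels", {
  cfg <- detection_config()
  lab0 <- mobility_state(track_signal(rep(0, 60), "%", 25), cfg)
  lab30 <- mobility_state(track_signal(rep(30, 60), "%", 25), cfg)
  lab70 <- mobility_state(track_signal(rep(70, 60), "%", 25), cfg)
  expect_true(all(lab0 == "Immobile"))
  expect_true(all(lab30 == "Mobile"))
  expect_true(all(lab70 == "HighlyMobile"))

  set.seed(13)
  for (rep in 1:10) {
    lab <- mobility_state(track_signal(runif(500, 0, 100), "%", 25), cfg)
    expect_false(any(is.na(lab)))
    expect_true(all(levels(lab) == c("Immobile", "Mobile", "HighlyMobile")))
  }
})

test_that("Multi Condition 1 is the stated four-way conjunction", {
  cfg <- detection_config()
  # a single 4 cm/s blip inside a quiet window: moving true at the blip while
  # the 100-sample average stays tiny
  ser <- make_speed_series(c(rep(0, 200), 4, rep(0, 200)), elong = 70, angle = 10)
  mc1 <- multi_condition_1(ser, cfg)
  expect_true(mc1[201])

  fat <- make_speed_series(c(rep(0, 200), 4, rep(0, 200)), elong = 80, angle = 10)
  expect_false(multi_condition_1(fat, cfg)[201])

  bent <- make_speed_series(c(rep(0, 200), 4, rep(0, 200)), elong = 70, angle = 30)
  expect_false(multi_condition_1(bent, cfg)[201])

  # not moving: velocity below the start threshold throughout
  quiet <- make_speed_series(rep(0.5, 401), elong = 70, angle = 10)
  expect_false(any(multi_condition_1(quiet, cfg)))

  # sustained walking: moving true but the 100-sample average is too high
  walk <- make_speed_series(rep(10, 401), elong = 70, angle = 10)
  expect_false(any(multi_condition_1(walk, cfg)))
})

test_that("Multi Condition 2 requires low acceleration plus all three points moving", {
  cfg <- detection_config()
  drift <- make_speed_series(rep(5, 100))
  mc2 <- multi_condition_2(drift, cfg)
  expect_true(all(mc2[3:100]))

  # nose pinned: its movement state never turns on
  pinned <- drift
  pinned$nose[, 1] <- 15
  expect_false(any(multi_condition_2(pinned, cfg)))

  # a jump in center velocity big enough to break the acceleration bound
  jumpy <- make_speed_series(c(rep(5, 50), rep(13, 50)))
  a <- as.numeric(compute_acceleration(compute_velocity(jumpy, "center")))
  expect_false(multi_condition_2(jumpy, cfg)[which.max(a)])

  allmiss <- drift
  allmiss$nose[] <- NA
  expect_error(multi_condition_2(allmiss, cfg), "trajectory-only")
})

test_that("relaxing any multi-condition bound never removes a true sample", {
  ser <- random_series(31, n_max = 2000)
  base <- detection_config()
  relaxed <- detection_config(mc1_avg_vel_max_cms = 0.9, mc1_elong_max_pct = 95,
                              mc1_angle_max_deg = 40, mc2_accel_max_cms2 = 400)
  sigb <- detection_signals(ser, base)
  sigr <- detection_signals(ser, relaxed)
  expect_true(all(sigr$mc1[sigb$mc1 %in% TRUE] %in% TRUE))
  expect_true(all(sigr$mc2[sigb$mc2 %in% TRUE] %in% TRUE))
})

test_that("state traces export one audited row per sample", {
  ser <- make_speed_series(c(rep(0, 100), 30, 35, 30, rep(0, 100)))
  cfg <- full_window_cfg()
  path <- withr::local_tempfile(fileext = ".csv")
  write_state_trace(ser, cfg, path)
  tr <- utils::read.csv(path)
  expect_equal(nrow(tr), length(ser))
  expect_named(tr, c("time_s", "moving", "mobility_pct", "mobility_state", "mc1", "mc2"))
})
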