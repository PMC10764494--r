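test_that("a zero-rate simulation has no jerks and bouts tile the session", {
  sim <- simulate_session(simulation_config(duration_s = 600, seed = 3,
                                            jerk_rate_per_h = 0))
  expect_equal(nrow(sim$truth$jerks), 0L)
  b <- sim$truth$bouts
  expect_equal(b$start_s[1], 0)
  expect_equal(b$end_s[nrow(b)], 600)
  expect_equal(b$start_s[-1], b$end_s[-nrow(b)])
  expect_true(all(b$label %in% c("explore", "sleep", "groom")))
  expect_equal(nrow(validate_series(sim$series)), 0L)
})

test_that("identical seeds give bit-identical sessions, different seeds differ", {
  cfg <- simulation_config(duration_s = 200, seed = 17, jerk_rate_per_h = 20,
                           initial_explore_s = 30)
  a <- simulate_session(cfg)
  b <- simulate_session(cfg)
  expect_identical(a$series, b$series)
  expect_identical(a$truth, b$truth)
  c <- simulate_session(simulation_config(duration_s = 200, seed = 18,
                                          jerk_rate_per_h = 20,
                                          initial_explore_s = 30))
  expect_false(identical(a$series$center, c$series$center))
})

test_that("jerk times lie inside sleep bouts", {
  sim <- simulate_session(simulation_config(duration_s = 3600, seed = 23,
                                            initial_explore_s = 300,
                                            jerk_rate_per_h = 20))
  expect_gt(nrow(sim$truth$jerks), 0)
  b <- sim$truth$bouts
  for (tj in sim$truth$jerks$time_s) {
    k <- which(b$start_s <= tj & b$end_s > tj)
    expect_identical(b$label[k], "sleep")
  }
})

test_that("injected jerk counts follow the configured Poisson rate", {
  # rate 4/h over the sleep time actually scheduled; 20 seeds pooled
  counts <- numeric(20)
  expected <- numeric(20)
  for (s in seq_len(20)) {
    sim <- simulate_session(simulation_config(duration_s = 7200, seed = 400 + s,
                                              initial_explore_s = 600,
                                              jerk_rate_per_h = 4, pair_prob = 0))
    b <- sim$truth$bouts
    sleep_h <- sum(b$end_s[b$label == "sleep"] - b$start_s[b$label == "sleep"]) / 3600
    counts[s] <- nrow(sim$truth$jerks)
    expected[s] <- 4 * sleep_h
  }
  lambda <- sum(expected)
  expect_lt(abs(sum(counts) - lambda), 3 * sqrt(lambda) + 3)
})

test_that("noise-free measured jerk peaks stay within the configured band", {
  scfg <- simulation_config(duration_s = 3600, seed = 31, initial_explore_s = 200,
                            jerk_rate_per_h = 15, tracking_noise_sd_cm = 0,
                            dropout_prob_per_sample = 0)
  sim <- simulate_session(scfg)
  expect_gt(nrow(sim$truth$jerks), 2)
  v <- as.numeric(compute_velocity(sim$series, "center"))
  fs <- sim$series$sample_rate_hz
  for (r in seq_len(nrow(sim$truth$jerks))) {
    i0 <- round(sim$truth$jerks$time_s[r] * fs) + 1
    span <- i0:min(length(v), i0 + ceiling(sim$truth$jerks$duration_s[r] * fs) + 2)
    peak <- max(v[span], na.rm = TRUE)
    expect_gte(peak, sim$truth$jerks$peak_cms[r] * 0.9)
    expect_lte(peak, sim$truth$jerks$peak_cms[r] * 1.1)
  }
})

test_that("sleep is sub-threshold: raw velocity below the movement stop level", {
  scfg <- simulation_config(duration_s = 3600, seed = 37, initial_explore_s = 300,
                            jerk_rate_per_h = 2)
  sim <- simulate_session(scfg)
  v <- as.numeric(compute_velocity(interpolate_gaps(sim$series, 1), "center"))
  fs <- sim$series$sample_rate_hz
  b <- sim$truth$bouts
  insleep <- rep(FALSE, length(v))
  for (k in which(b$label == "sleep"))
    insleep[(floor(b$start_s[k] * fs) + 1):floor(b$end_s[k] * fs)] <- TRUE
  # exclude jerks (and their recovery) +/- 2 s
  for (tj in sim$truth$jerks$time_s) {
    lo <- max(1, round((tj - 2) * fs)); hi <- min(length(v), round((tj + 4) * fs))
    insleep[lo:hi] <- FALSE
  }
  frac <- mean(v[insleep] < 2.25, na.rm = TRUE)
  expect_gte(frac, 0.99)
})

test_that("consecutive-jerk partners arrive 1-20 s after their base event", {
  sim <- simulate_session(simulation_config(duration_s = 14400, seed = 41,
                                            jerk_rate_per_h = 6, pair_prob = 0.5))
  j <- sim$truth$jerks
  paired <- j[!is.na(j$pair_id), ]
  expect_gt(nrow(paired), 0)
  for (pid in unique(paired$pair_id)) {
    pp <- paired[paired$pair_id == pid, ]
    expect_equal(nrow(pp), 2L)
    gap <- diff(sort(pp$time_s))
    expect_gte(gap, 1); expect_lte(gap, 20)
  }
})

test_that("impossible configurations are refused", {
  expect_error(simulation_config(duration_s = -1), "duration")
  expect_error(simulation_config(jerk_rate_per_h = -2), "rate")
  expect_error(simulation_config(pair_prob = 1.5), "pair_prob")
  expect_error(simulation_config(jerk_dur_s_range = c(0.5, 20)), "sleep bout")
  expect_error(simulation_config(jerk_peak_cms_range = c(50, 30)), "increasing")
})

test_that("ground truth survives a JSON round trip", {
  sim <- simulate_session(simulation_config(duration_s = 1200, seed = 47,
                                            initial_explore_s = 100,
                                            jerk_rate_per_h = 20))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$jerks$time_s, sim$truth$jerks$time_s, tolerance = 1e-9)
  expect_equal(back$bouts$label, sim$truth$bouts$label)
})
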