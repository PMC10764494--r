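test_that("event matching follows the one-to-one greedy-by-proximity rule", {
  perfect <- match_events(c(10, 50, 90), c(10, 50, 90))
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$onset_errors_s, c(0, 0, 0))

  # 10 truth events, 9 detections of which 8 match within tolerance
  truth <- seq(10, 100, by = 10)
  det <- c(truth[1:8] + 0.5, 55)   # the 9th lands 5 s from anything
  m <- match_events(det, truth, tolerance_s = 2)
  expect_equal(m$tp, 8); expect_equal(m$fp, 1); expect_equal(m$fn, 2)
  expect_equal(m$precision, 8 / 9)
  expect_equal(m$recall, 0.8)

  # two detections near one truth event: one tp, one fp
  m2 <- match_events(c(10.2, 10.8), 10)
  expect_equal(m2$tp, 1); expect_equal(m2$fp, 1); expect_equal(m2$fn, 0)
  # the closer one is taken
  expect_equal(m2$matches$detected_s, 10.2)

  expect_equal(match_events(numeric(0), numeric(0))$precision, 1)
  expect_error(match_events(1, 1, tolerance_s = -1), "non-negative")
})

test_that("matching is invariant to input ordering", {
  set.seed(5)
  truth <- sort(runif(15, 0, 1000))
  det <- sort(c(truth[1:10] + rnorm(10, 0, 0.5), runif(3, 0, 1000)))
  a <- match_events(det, truth)
  b <- match_events(sample(det), sample(truth))
  expect_equal(a$tp, b$tp); expect_equal(a$fp, b$fp); expect_equal(a$fn, b$fn)
})

test_that("two-way ANOVA agrees with the closed-form balanced oracle", {
  set.seed(101)
  for (rep in 1:5) {
    d <- expand.grid(g = c("wt", "mut"), age = c("2m", "4m", "6m"),
                     r = 1:5, KEEP.OUT.ATTRS = FALSE)
    d$y <- rnorm(nrow(d), 10, 3) + (d$g == "mut") * rnorm(1, 2, 1)
    got <- two_way_anova_sidak(d, "y", "g", "age")
    want <- balanced_anova_oracle(d$y, d$g, d$age)
    expect_equal(got$table$F[got$table$term == "g"], want$F_A, tolerance = 1e-8)
    expect_equal(got$table$F[got$table$term == "age"], want$F_B, tolerance = 1e-8)
    expect_equal(got$table$F[got$table$term == "g:age"], want$F_AB, tolerance = 1e-8)
  }
})

test_that("flat cell means give zero F and Sidak adjustment behaves", {
  d <- expand.grid(g = c("a", "b"), age = c("x", "y"), r = 1:4)
  d$y <- rep(c(1, 2, 3, 4), each = 4)  # every cell holds the same four values
  res <- two_way_anova_sidak(d, "y", "g", "age")
  expect_true(all(abs(res$table$F) < 1e-10))
  expect_true(all(res$pairwise$p_sidak >= res$pairwise$p - 1e-12))
  expect_equal(res$pairwise$m[1], 2)
  expect_equal(res$pairwise$p_sidak, 1 - (1 - res$pairwise$p)^2, tolerance = 1e-12)

  # single age level: m = 1 so adjusted p equals raw p
  d1 <- d[d$age == "x", ]
  res1 <- two_way_anova_sidak(d1, "y", "g", "age")
  expect_equal(res1$pairwise$p_sidak, res1$pairwise$p, tolerance = 1e-12)
})

test_that("empty design cells are named in the error", {
  d <- expand.grid(g = c("a", "b"), age = c("x", "y"), r = 1:3)
  d$y <- rnorm(nrow(d))
  d <- d[!(d$g == "b" & d$age == "y"), ]
  expect_error(two_way_anova_sidak(d, "y", "g", "age"), "b:y")
})

test_that("the repeated-measures variant runs with a subject error term", {
  set.seed(7)
  d <- expand.grid(subj = sprintf("s%02d", 1:8), age = c("2m", "4m"))
  d$g <- ifelse(as.integer(sub("s", "", d$subj)) <= 4, "wt", "mut")
  d$y <- rnorm(nrow(d), 10) + (d$g == "mut") * 3
  res <- two_way_anova_sidak(d, "y", "g", "age", subject = "subj", repeated = TRUE)
  expect_true("g" %in% res$table$term)
  expect_true(all(res$table$p >= 0 & res$table$p <= 1, na.rm = TRUE))
})

test_that("cohort summaries report cells and skip ANOVA for degenerate designs", {
  summaries <- data.frame(session_id = sprintf("s%d", 1:6),
                          n_events = c(5, 7, 6, 1, 0, 2))
  design <- data.frame(session_id = sprintf("s%d", 1:6),
                       animal_id = sprintf("a%d", 1:6),
                       genotype = rep(c("mut", "wt"), each = 3))
  cs <- summarize_cohort(summaries, design)
  expect_equal(nrow(cs$cells), 2)
  expect_equal(cs$cells$mean[cs$cells$genotype == "mut"], 6)
  expect_false(is.null(cs$anova))

  one <- summarize_cohort(summaries[1:3, ], design[1:3, ])
  expect_null(one$anova)
  expect_match(one$notice, "skipped")

  expect_error(summarize_cohort(data.frame(session_id = "zz", n_events = 1), design),
               "zz")
})

test_that("genotype effects separate strongly different simulated rates", {
  # desk-scale power check on count summaries drawn from the count model
  set.seed(77)
  p <- replicate(40, {
    mut <- rpois(8, 12); wt <- rpois(8, 0.6)
    d <- data.frame(y = c(mut, wt),
                    g = rep(c("mut", "wt"), each = 8), age = "a")
    two_way_anova_sidak(d, "y", "g", "age")$table$p[1]
  })
  expect_gte(mean(p < 0.01), 0.95)
})

test_that("the diagnostic event-window plot renders without error", {
  ser <- inject_test_burst(make_still_series(2000), at_s = 40, peak = 40)
  cfg <- full_window_cfg()
  ev <- detect_events(ser, cfg)
  png_path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(png_path, width = 600, height = 400)
  on.exit(grDevices::dev.off(), add = TRUE)
  rng <- plot_event_window(ser, cfg, center_s = 40, events = ev)
  expect_length(rng, 2)
  expect_error(plot_event_window(ser, cfg, center_s = 1e6), "no samples")
})
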