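#' Match detected events against ground truth
#'
#' One-to-one matching by onset proximity: all detected/truth pairs within
#' `tolerance_s` are considered in order of increasing onset error and
#' assigned greedily, so each detection matches at most one truth event and
#' vice versa. Unmatched detections are false positives, unmatched truth
#' events false negatives.
#'
#' @param detected Event table (rows with `accepted %in% TRUE` are used) or a
#'   numeric vector of onset times in s.
#' @param truth A `ground_truth` object or numeric vector of jerk times in s.
#' @param tolerance_s Maximum |onset error| for a match (default 2 s).
#' @return A list of class `match_result`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, `onset_errors_s`, `tolerance_s`, `matches` (data frame
#'   `detected_s`, `truth_s`, `error_s`).
#' @export
match_events <- function(detected, truth, tolerance_s = 2.0) {
  if (tolerance_s < 0) stop("'tolerance_s' must be non-negative")
  d <- if (is.numeric(detected)) detected
       else detected$onset_s[detected$accepted %in% TRUE]
  g <- if (is.numeric(truth)) truth else truth$jerks$time_s
  d <- sort(d); g <- sort(g)
  pairs <- expand.grid(di = seq_along(d), gi = seq_along(g))
  if (nrow(pairs)) {
    pairs$err <- abs(d[pairs$di] - g[pairs$gi])
    pairs <- pairs[pairs$err <= tolerance_s, , drop = FALSE]
    pairs <- pairs[order(pairs$err, pairs$di, pairs$gi), , drop = FALSE]
  }
  used_d <- logical(length(d)); used_g <- logical(length(g))
  sel <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    di <- pairs$di[r]; gi <- pairs$gi[r]
    if (!used_d[di] && !used_g[gi]) {
      used_d[di] <- TRUE; used_g[gi] <- TRUE
      sel <- c(sel, r)
    }
  }
  m <- pairs[sel, , drop = FALSE]
  tp <- nrow(m); fp <- length(d) - tp; fn <- length(g) - tp
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn),
    f1 = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    onset_errors_s = d[m$di] - g[m$gi],
    tolerance_s = tolerance_s,
    matches = data.frame(detected_s = d[m$di], truth_s = g[m$gi],
                         error_s = d[m$di] - g[m$gi])
  ), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tp %d fp %d fn %d | precision %.3f recall %.3f f1 %.3f (tol %.1f s)\n",
              x$tp, x$fp, x$fn, x$precision, x$recall, x$f1, x$tolerance_s))
  invisible(x)
}

#' Evaluate a detection run against simulator ground truth
#'
#' Restricts both the accepted detections and the ground-truth jerks to the
#' analysis window before matching, since events outside the window are by
#' definition not quantified.
#'
#' @param events Classified event table.
#' @param truth `ground_truth` from [simulate_session()].
#' @param cfg The [detection_config()] used.
#' @param tolerance_s Onset matching tolerance, s.
#' @return A `match_result`.
#' @export
evaluate_detection <- function(events, truth, cfg = attr(events, "config"),
                               tolerance_s = 2.0) {
  g <- truth$jerks$time_s
  g <- g[g >= cfg$analysis_start_s & g <= cfg$analysis_end_s]
  d <- events$onset_s[events$accepted %in% TRUE]
  d <- d[d >= cfg$analysis_start_s & d <= cfg$analysis_end_s]
  match_events(d, g, tolerance_s)
}

#' Two-way ANOVA with Sidak-adjusted group comparisons
#'
#' Standard two-factor analysis of the per-session event counts (or any
#' response): Type II sums of squares (conventional default for the mild
#' imbalance of real cohorts, e.g. N = 15 vs 16), followed by planned
#' factor-A comparisons within each level of factor B using the pooled
#' residual variance, Sidak-adjusted over the m = (number of B levels)
#' comparisons: `p_adj = 1 - (1 - p)^m`. Cell means and SDs are reported for
#' every cell. A repeated-measures variant (`repeated = TRUE`, subjects
#' crossed with factor B) uses an error term for subject.
#'
#' @param data Data frame with one row per observation.
#' @param response,factor_a,factor_b,subject Column names; `subject` is only
#'   needed for the repeated-measures variant.
#' @param repeated Use the repeated-measures error structure.
#' @return A list of class `anova_result`: `table` (factor F/df/p), `cells`
#'   (mean/SD/n per cell), `pairwise` (per-B-level A comparisons with raw and
#'   Sidak-adjusted p, m recorded), `model`.
#' @export
two_way_anova_sidak <- function(data, response, factor_a, factor_b,
                                subject = NULL, repeated = FALSE) {
  data <- as.data.frame(data)
  for (col in c(response, factor_a, factor_b))
    if (!col %in% names(data)) stop(sprintf("column '%s' not found", col))
  data$.y <- data[[response]]
  data$.A <- factor(data[[factor_a]])
  data$.B <- factor(data[[factor_b]])
  if (nlevels(data$.A) < 2) stop("factor A needs at least 2 levels")
  cells <- stats::aggregate(.y ~ .A + .B, data, function(v)
    c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  cells <- cbind(cells[c(".A", ".B")], as.data.frame(cells$.y))
  names(cells) <- c(factor_a, factor_b, "mean", "sd", "n")
  empty <- with(expand.grid(A = levels(data$.A), B = levels(data$.B)),
                !paste(A, B) %in% paste(cells[[factor_a]], cells[[factor_b]]))
  if (any(empty))
    stop("empty design cell(s): ",
         paste(with(expand.grid(A = levels(data$.A), B = levels(data$.B)),
                    paste0(A, ":", B))[empty], collapse = ", "))

  two_b <- nlevels(data$.B) >= 2
  if (repeated) {
    if (is.null(subject)) stop("'subject' is required for the repeated-measures variant")
    data$.S <- factor(data[[subject]])
    form <- if (two_b) .y ~ .A * .B + Error(.S) else .y ~ .A + Error(.S)
    fit <- stats::aov(form, data = data)
    sm <- summary(fit)
    tab <- do.call(rbind, lapply(sm, function(s) {
      d <- as.data.frame(s[[1]])
      d$term <- trimws(rownames(d))
      d
    }))
    tab <- tab[tab$term != "Residuals", c("term", "Df", "F value", "Pr(>F)")]
    names(tab) <- c("term", "df", "F", "p")
    rownames(tab) <- NULL
    resid_ms <- {
      within_tab <- as.data.frame(sm[[length(sm)]][[1]])
      as.numeric(within_tab["Residuals", "Mean Sq"])
    }
    resid_df <- as.data.frame(sm[[length(sm)]][[1]])["Residuals", "Df"]
    model <- fit
  } else {
    small <- stats::aggregate(.y ~ .A + .B, data, length)
    if (any(small$.y < 2) && two_b)
      warning("some cells have fewer than 2 observations; F tests may be degenerate")
    model <- if (two_b) stats::lm(.y ~ .A * .B, data = data)
             else stats::lm(.y ~ .A, data = data)
    a2 <- car::Anova(model, type = 2)
    tab <- data.frame(term = rownames(a2), df = a2$Df, F = a2$`F value`,
                      p = a2$`Pr(>F)`)
    tab <- tab[tab$term != "Residuals", ]
    rownames(tab) <- NULL
    resid_ms <- sum(stats::residuals(model)^2) / stats::df.residual(model)
    resid_df <- stats::df.residual(model)
  }
  tab$term <- gsub("\\.A", factor_a, gsub("\\.B", factor_b, tab$term))

  # planned within-B factor-A comparisons, Sidak family = one per B level
  m <- nlevels(data$.B)
  la <- levels(data$.A)
  pw <- list()
  for (bl in levels(data$.B)) {
    combs <- utils::combn(la, 2)
    for (j in seq_len(ncol(combs))) {
      g1 <- data$.y[data$.A == combs[1, j] & data$.B == bl]
      g2 <- data$.y[data$.A == combs[2, j] & data$.B == bl]
      se <- sqrt(resid_ms * (1 / length(g1) + 1 / length(g2)))
      tstat <- (mean(g1) - mean(g2)) / se
      p <- 2 * stats::pt(-abs(tstat), resid_df)
      pw[[length(pw) + 1L]] <- data.frame(
        comparison = sprintf("%s vs %s", combs[1, j], combs[2, j]),
        level = bl, estimate = mean(g1) - mean(g2), t = tstat,
        df = resid_df, p = p, p_sidak = 1 - (1 - p)^m)
    }
  }
  pairwise <- do.call(rbind, pw)
  pairwise$m <- m
  structure(list(table = tab, cells = cells, pairwise = pairwise,
                 model = model, repeated = repeated),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result>%s\n", if (x$repeated) " (repeated measures)" else ""))
  print(x$table, row.names = FALSE)
  cat("cell means +/- SD:\n")
  print(x$cells, row.names = FALSE)
  cat(sprintf("pairwise (Sidak, m = %d):\n", x$pairwise$m[1]))
  print(x$pairwise[setdiff(names(x$pairwise), "m")], row.names = FALSE)
  invisible(x)
}

#' Summarize a cohort of sessions
#'
#' Joins per-session summaries ([count_events()]) with a genotype-by-age
#' design, reports per-cell mean and SD of the event counts, runs the
#' two-way ANOVA with Sidak comparisons where the design allows it, and
#' builds the per-animal trajectory table across ages.
#'
#' @param summaries Data frame with columns `session_id` and `n_events` (one
#'   row per session), e.g. `rbind` of [count_events()] outputs.
#' @param design Data frame with columns `session_id`, `animal_id`,
#'   `genotype`, and optionally `age` (a single common age is assumed if
#'   absent).
#' @return A list of class `cohort_summary`: `table` (joined rows), `cells`,
#'   `anova` (`NULL` with a `notice` when the design is degenerate),
#'   `per_animal` (wide animal-by-age counts).
#' @export
summarize_cohort <- function(summaries, design) {
  need <- c("session_id", "animal_id", "genotype")
  if (!all(need %in% names(design)))
    stop("design must have columns: ", paste(need, collapse = ", "))
  if (!"age" %in% names(design)) design$age <- "single"
  unmatched <- setdiff(summaries$session_id, design$session_id)
  if (length(unmatched))
    stop("sessions missing from design: ", paste(unmatched, collapse = ", "))
  tab <- merge(summaries, design, by = "session_id")
  cells <- stats::aggregate(n_events ~ genotype + age, tab, function(v)
    c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  cells <- cbind(cells[c("genotype", "age")], as.data.frame(cells$n_events))
  anova <- NULL; notice <- NULL
  if (length(unique(tab$genotype)) >= 2 && all(table(tab$genotype, tab$age) >= 2)) {
    anova <- two_way_anova_sidak(tab, "n_events", "genotype", "age")
  } else {
    notice <- "ANOVA skipped: need >= 2 genotypes and >= 2 sessions per cell"
  }
  per_animal <- stats::reshape(tab[c("animal_id", "genotype", "age", "n_events")],
                               idvar = c("animal_id", "genotype"),
                               timevar = "age", direction = "wide")
  structure(list(table = tab, cells = cells, anova = anova, notice = notice,
                 per_animal = per_animal), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$cells, row.names = FALSE)
  if (!is.null(x$notice)) cat(x$notice, "\n") else print(x$anova)
  invisible(x)
}

#' Default simulation benchmark
#'
#' Simulates a two-genotype cohort (default 12 "mutant" sessions at 4 jerks/h
#' and 12 "wild-type" sessions at 0.2 jerks/h, 4-h sessions at 25 Hz), runs
#' the full detection pipeline on every session's trajectories, evaluates
#' detections against ground truth within the analysis window, and
#' summarizes the cohort.
#'
#' @param seed Master seed; per-session seeds are derived deterministically.
#' @param n_per_group Sessions per genotype.
#' @param rate_mutant,rate_wt Injected jerk rates per hour.
#' @param duration_s Session length, s.
#' @param cfg Detection configuration.
#' @param tolerance_s Event-matching tolerance, s.
#' @return A list of class `benchmark_result`: `sessions` (per-session data
#'   frame with counts and match statistics), `overall` (pooled tp/fp/fn,
#'   precision, recall, f1), `cohort` (a `cohort_summary`), `onset_errors_s`
#'   (pooled onset errors of all matched events).
#' @export
benchmark_cohort <- function(seed = 1L, n_per_group = 12L,
                             rate_mutant = 4, rate_wt = 0.2,
                             duration_s = 14400, cfg = detection_config(),
                             tolerance_s = 2.0) {
  rows <- list()
  tp <- fp <- fn <- 0L
  summaries <- list()
  design <- list()
  onset_errors <- numeric(0)
  k <- 0L
  for (geno in c("mutant", "wt")) {
    rate <- if (geno == "mutant") rate_mutant else rate_wt
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      scfg <- simulation_config(seed = as.integer(seed) * 100L + k,
                                duration_s = duration_s,
                                jerk_rate_per_h = rate)
      sim <- simulate_session(scfg)
      sim$series$session_id <- sprintf("%s-%02d", geno, i)
      ev <- detect_events(sim$series, cfg)
      mr <- evaluate_detection(ev, sim$truth, cfg, tolerance_s)
      cnt <- count_events(ev, cfg, session_id = sim$series$session_id)
      tp <- tp + mr$tp; fp <- fp + mr$fp; fn <- fn + mr$fn
      onset_errors <- c(onset_errors, mr$onset_errors_s)
      rows[[k]] <- cbind(cnt, genotype = geno, tp = mr$tp, fp = mr$fp, fn = mr$fn,
                         n_truth = mr$tp + mr$fn)
      summaries[[k]] <- cnt
      design[[k]] <- data.frame(session_id = cnt$session_id,
                                animal_id = sprintf("%s-animal-%02d", geno, i),
                                genotype = geno)
    }
  }
  sessions <- do.call(rbind, rows)
  overall <- list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = if (tp + fn == 0) 1 else tp / (tp + fn),
    f1 = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn))
  cohort <- summarize_cohort(do.call(rbind, summaries), do.call(rbind, design))
  structure(list(sessions = sessions, overall = overall, cohort = cohort,
                 onset_errors_s = onset_errors),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %d sessions | precision %.3f recall %.3f f1 %.3f\n",
              nrow(x$sessions), x$overall$precision, x$overall$recall, x$overall$f1))
  print(x$cohort)
  invisible(x)
}
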