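# Independent brute-force candidate scan: applies the burst criteria
# literally with plain loops over samples, sharing no code with
# detect_candidates() beyond the per-sample state signals it consumes.
brute_force_candidates <- function(series, cfg) {
  sig <- detection_signals(series, cfg)
  ser <- sig$series
  fs <- ser$sample_rate_hz
  n <- length(ser$t)
  v <- as.numeric(sig$velocity)
  imm <- sig$mobility_state == "Immobile"
  imm[is.na(imm)] <- FALSE
  mc <- (sig$mc1 %in% TRUE) | (sig$mc2 %in% TRUE)

  above <- function(i) !is.na(v[i]) && v[i] > cfg$burst_vel_min_cms
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (above(i)) {
      j <- i
      while (j < n && above(j + 1L)) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  # merge runs separated by fewer than merge_gap_s of sub-threshold samples
  merged <- list()
  for (r in runs) {
    if (length(merged)) {
      prev <- merged[[length(merged)]]
      if ((r[1] - prev[2] - 1L) / fs < cfg$merge_gap_s) {
        merged[[length(merged)]] <- c(prev[1], r[2])
        next
      }
    }
    merged[[length(merged) + 1L]] <- r
  }
  ctx <- round(cfg$mc_context_s * fs)
  out <- list()
  for (r in merged) {
    i0 <- r[1]; i1 <- r[2]
    if (ser$t[i0] < cfg$analysis_start_s || ser$t[i0] > cfg$analysis_end_s) next
    if ((i1 - i0 + 1L) / fs > cfg$burst_max_dur_s) next            # (a)
    peak <- -Inf
    for (k in i0:i1) if (v[k] > peak) peak <- v[k]
    if (peak > cfg$burst_vel_max_cms) next                          # (b)
    # (c) walk back over at most pre_gap_max_s of non-Immobile samples, then
    # count the contiguous Immobile run
    lag_allow <- floor(cfg$pre_gap_max_s * fs + 1e-9)
    j <- i0 - 1L; lag <- 0L
    while (j >= 1L && !imm[j] && lag < lag_allow) { j <- j - 1L; lag <- lag + 1L }
    run_len <- 0L
    if (j >= 1L && imm[j]) while (j >= 1L && imm[j]) { j <- j - 1L; run_len <- run_len + 1L }
    if (run_len / fs < cfg$pre_immobile_min_s - 1e-9) next
    # (d) a multi-condition hit inside the context window
    w0 <- max(1L, i0 - ctx); w1 <- min(n, i1 + ctx)
    hit <- FALSE
    for (k in w0:w1) if (mc[k]) { hit <- TRUE; break }
    if (!hit) next
    out[[length(out) + 1L]] <- data.frame(
      onset_idx = i0, offset_idx = i1, peak_velocity_cms = peak,
      pre_immobile_s = run_len / fs,
      mc1_hit = any(sig$mc1[w0:w1] %in% TRUE),
      mc2_hit = any(sig$mc2[w0:w1] %in% TRUE))
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(onset_idx = integer(0), offset_idx = integer(0),
                  peak_velocity_cms = numeric(0), pre_immobile_s = numeric(0),
                  mc1_hit = logical(0), mc2_hit = logical(0))
}

# Compare detect_candidates() with the brute-force scan on one series.
expect_oracle_equal <- function(series, cfg) {
  got <- as.data.frame(detect_candidates(series, cfg))
  want <- brute_force_candidates(series, cfg)
  cols <- c("onset_idx", "offset_idx", "peak_velocity_cms", "pre_immobile_s",
            "mc1_hit", "mc2_hit")
  got <- got[cols]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want, tolerance = 1e-12,
               label = sprintf("candidates for '%s'", series$session_id))
}

# Closed-form balanced two-way ANOVA sums-of-squares decomposition.
balanced_anova_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  gm <- mean(y)
  a <- nlevels(A); b <- nlevels(B); nr <- length(y) / (a * b)
  ssA <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssB <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cellm <- tapply(y, list(A, B), mean)
  ssCells <- nr * sum((cellm - gm)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((y - cellm[cbind(A, B)])^2)
  dfA <- a - 1; dfB <- b - 1; dfAB <- dfA * dfB; dfE <- length(y) - a * b
  mse <- ssE / dfE
  list(F_A = (ssA / dfA) / mse, F_B = (ssB / dfB) / mse,
       F_AB = (ssAB / dfAB) / mse, df = c(dfA, dfB, dfAB, dfE))
}
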