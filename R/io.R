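#' Read a tracking table
#'
#' Parses the plain-text tracking dialect used throughout this package:
#' a CSV with header
#' `time_s,center_x_cm,center_y_cm,nose_x_cm,nose_y_cm,tail_x_cm,tail_y_cm,elongation_pct,body_angle_deg`,
#' one row per sample, UTF-8, `.` decimal separator. Empty fields mark samples
#' the tracker lost; such rows are kept (never dropped) with `missing = TRUE`.
#' Lines starting with `#` before the header are treated as comments; they may
#' carry `key: value` metadata (`session_id`, `arena_w_cm`, `arena_h_cm`,
#' `sample_rate_hz`) written by [write_tracking_table()].
#'
#' @param path Path to the CSV file.
#' @param sample_rate_hz Optional sampling rate; if `NULL` it is taken from the
#'   file's metadata comments or, failing that, inferred as 1/median time step.
#' @return A validated [tracking_series()]. Rows in equals samples out.
#' @export
read_tracking_table <- function(path, sample_rate_hz = NULL) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  lines <- readLines(path, encoding = "UTF-8")
  is_comment <- grepl("^\\s*#", lines)
  body_at <- which(!is_comment & nzchar(trimws(lines)))
  if (!length(body_at)) stop(sprintf("'%s': no header line found", path))
  meta <- parse_meta_comments(lines[is_comment & seq_along(lines) < body_at[1]])

  expected <- c("time_s", "center_x_cm", "center_y_cm", "nose_x_cm", "nose_y_cm",
                "tail_x_cm", "tail_y_cm", "elongation_pct", "body_angle_deg")
  header <- strsplit(trimws(lines[body_at[1]]), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), expected)) {
    bad <- setdiff(trimws(header), expected)
    miss <- setdiff(expected, trimws(header))
    stop(sprintf("'%s': malformed header; unexpected column(s): %s; missing column(s): %s",
                 path,
                 if (length(bad)) paste(bad, collapse = ", ") else "<none>",
                 if (length(miss)) paste(miss, collapse = ", ") else "<none>"))
  }
  df <- utils::read.csv(text = lines[body_at], header = TRUE,
                        colClasses = "numeric", na.strings = "")
  names(df) <- expected

  if (nrow(df) > 1) {
    bad <- which(diff(df$time_s) <= 0)
    if (length(bad))
      stop(sprintf("'%s': time not strictly increasing at row %d", path, bad[1] + 1L))
  }
  if (is.null(sample_rate_hz)) sample_rate_hz <- meta$sample_rate_hz
  if (is.null(sample_rate_hz)) {
    if (nrow(df) < 2) stop("cannot infer sample rate from fewer than 2 rows; pass 'sample_rate_hz'")
    sample_rate_hz <- 1 / stats::median(diff(df$time_s))
  }
  tracking_series(
    session_id = meta$session_id %||% tools::file_path_sans_ext(basename(path)),
    sample_rate_hz = sample_rate_hz,
    t = df$time_s,
    center = cbind(df$center_x_cm, df$center_y_cm),
    nose = cbind(df$nose_x_cm, df$nose_y_cm),
    tail = cbind(df$tail_x_cm, df$tail_y_cm),
    elongation_pct = df$elongation_pct,
    body_angle_deg = df$body_angle_deg,
    arena_w_cm = meta$arena_w_cm %||% 30,
    arena_h_cm = meta$arena_h_cm %||% 30
  )
}

parse_meta_comments <- function(comment_lines) {
  meta <- list()
  for (ln in comment_lines) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", ln))[[1]]
    if (length(m) == 3) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a tracking table
#'
#' Writes a [tracking_series()] in the dialect read by [read_tracking_table()],
#' with session metadata in leading `#` comments. Numeric fields are written
#' with 12 significant digits so that a write/read round trip reproduces every
#' field to better than 1e-9. Missing samples become rows with empty
#' coordinate/posture cells.
#'
#' @param series A `tracking_series`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tracking_table <- function(series, path) {
  df <- as.data.frame(series)
  if (any(series$missing))
    df[series$missing, setdiff(names(df), "time_s")] <- NA_real_
  fmt <- function(x) ifelse(is.na(x), "", formatC(x, format = "g", digits = 12))
  rows <- do.call(paste, c(lapply(df, fmt), sep = ","))
  out <- c(
    sprintf("# session_id: %s", series$session_id),
    sprintf("# sample_rate_hz: %s", formatC(series$sample_rate_hz, format = "g", digits = 12)),
    sprintf("# arena_w_cm: %g", series$arena_w_cm),
    sprintf("# arena_h_cm: %g", series$arena_h_cm),
    paste(names(df), collapse = ","),
    rows
  )
  ok <- tryCatch({
    writeLines(out, path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write tracking table to '%s'", path))
  invisible(path)
}

#' Write detected events
#'
#' `write_events_csv()` writes the event table as plain CSV;
#' `write_events_json()` embeds the detection configuration alongside the
#' events so a run can be audited and reproduced from its output alone.
#'
#' @param events An event data frame from [detect_events()] or
#'   [detect_candidates()].
#' @param path Output path.
#' @param cfg The [detection_config()] used (JSON variant only).
#' @param session_id Session identifier recorded in the output.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, session_id = attr(events, "session_id")) {
  out <- as.data.frame(events)[event_columns()]
  out <- cbind(session_id = rep(session_id %||% NA_character_, nrow(out)), out)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_events_csv
#' @export
write_events_json <- function(events, path, cfg = attr(events, "config"),
                              session_id = attr(events, "session_id")) {
  payload <- list(
    session_id = session_id %||% NA_character_,
    config = unclass(cfg),
    events = as.data.frame(events)[event_columns()]
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  structure(df[setdiff(names(df), "session_id")],
            session_id = df$session_id[1] %||% NA_character_,
            class = c("myoclonic_events", "data.frame"),
            row.names = seq_len(nrow(df)))
}

event_columns <- function() {
  c("onset_s", "offset_s", "peak_velocity_cms", "pre_immobile_s",
    "mc1_hit", "mc2_hit", "accepted", "rejection_reason", "pair_id",
    "magnitude_class")
}

#' Export per-sample state traces
#'
#' Writes the audit trace `time_s,moving,mobility_pct,mobility_state,mc1,mc2`
#' for a session, one row per sample.
#'
#' @param series A `tracking_series`.
#' @param cfg A [detection_config()].
#' @param path Output CSV path.
#' @param signals Optional pre-computed [detection_signals()] to avoid
#'   recomputation.
#' @return `path`, invisibly.
#' @export
write_state_trace <- function(series, cfg, path, signals = NULL) {
  s <- signals %||% detection_signals(series, cfg)
  df <- data.frame(time_s = series$t,
                   moving = as.logical(s$moving),
                   mobility_pct = round(as.numeric(s$mobility), 4),
                   mobility_state = as.character(s$mobility_state),
                   mc1 = as.logical(s$mc1),
                   mc2 = as.logical(s$mc2))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
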