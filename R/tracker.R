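#' Open a frame stack
#'
#' Accepts a directory of PNG frames (lexicographic order), a multi-page TIFF
#' file, or an in-memory list of grayscale matrices, and returns a uniform
#' accessor used by [estimate_background()] and [track_video()].
#'
#' @param x Directory path, `.tif`/`.tiff` path, or list of matrices.
#' @return A list with elements `n` (frame count) and `get(i)` (returns frame
#'   `i` as a matrix in \[0, 1\]).
#' @export
frame_source <- function(x) {
  to_gray <- function(img) {
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  }
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    files <- sort(list.files(x, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop(sprintf("no PNG frames found in '%s'", x))
    list(n = length(files), get = function(i) to_gray(png::readPNG(files[i])))
  } else if (is.character(x) && length(x) == 1L && grepl("\\.tiff?$", x)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF stacks")
    frames <- tiff::readTIFF(x, all = TRUE)
    list(n = length(frames), get = function(i) to_gray(frames[[i]]))
  } else if (is.list(x)) {
    list(n = length(x), get = function(i) to_gray(x[[i]]))
  } else stop("unsupported frame stack: pass a PNG directory, a TIFF file or a list of matrices")
}

#' Estimate the static background
#'
#' Per-pixel median over a uniform subsample of at most 200 frames. The
#' median is robust as long as the animal occupies any given pixel in fewer
#' than half of the sampled frames, which holds for a mouse moving about an
#' arena much larger than its body.
#'
#' @param frames Anything accepted by [frame_source()].
#' @param max_frames Subsample size cap.
#' @return A background matrix.
#' @export
estimate_background <- function(frames, max_frames = 200L) {
  src <- frame_source(frames)
  if (src$n < 10L) stop(sprintf("need at least 10 frames to estimate a background, got %d", src$n))
  idx <- unique(round(seq(1L, src$n, length.out = min(max_frames, src$n))))
  f1 <- src$get(idx[1])
  stack <- vapply(idx, function(i) as.numeric(src$get(i)),
                  numeric(length(f1)))
  med <- apply(stack, 1L, stats::median)
  matrix(med, nrow(f1), ncol(f1))
}

#' Segment the animal in one frame
#'
#' Thresholds the absolute difference to the background (Otsu's threshold by
#' default, fixed override available for degenerate illumination) and keeps
#' the largest connected foreground component. Frames whose difference image
#' never exceeds `min_contrast` yield an empty mask (animal absent).
#'
#' @param frame,background Matrices of identical shape.
#' @param thr Gray-level threshold on `|frame - background|`; `NULL` = Otsu.
#' @param min_contrast Minimum peak difference for the frame to be considered
#'   to contain the animal at all.
#' @return A logical mask matrix.
#' @export
segment_frame <- function(frame, background, thr = NULL, min_contrast = 0.1) {
  if (!identical(dim(frame), dim(background)))
    stop("frame and background have different shapes")
  d <- abs(frame - background)
  if (max(d) < min_contrast) return(matrix(FALSE, nrow(d), ncol(d)))
  if (is.null(thr)) thr <- EBImage::otsu(EBImage::Image(d), range = c(0, max(d)))
  mask <- d > thr
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Extract body points from a segmented frame
#'
#' From the largest-component mask: the center-point is the mask centroid;
#' the body axis is the principal axis of the pixel scatter; the two body
#' ends are the extreme pixels along that axis (averaged over the outermost
#' few for stability); the nose is the end with the brighter local intensity
#' and the tail-base is the opposite end pulled 15% toward the centroid.
#' Elongation is `100 * (1 - minor/major)` from the axis-length ratio
#' (`sqrt` of the eigenvalue ratio), so a circular blob scores 0 and a
#' stretched body approaches 100. The body angle is the deviation from
#' collinearity at the center: 180 degrees minus the angle enclosed by the
#' center-to-nose and center-to-tail vectors.
#'
#' @param mask Logical mask from [segment_frame()].
#' @param intensity The original frame (used only to orient head/tail).
#' @param px_per_cm Spatial calibration.
#' @param tip_k Number of extreme pixels averaged per body end.
#' @return A list: `center_xy`, `nose_xy`, `tail_xy` (cm), `elongation_pct`,
#'   `body_angle_deg`; all `NA` for an empty mask.
#' @export
extract_body_points <- function(mask, intensity, px_per_cm, tip_k = 5L) {
  pix <- which(mask, arr.ind = TRUE)
  if (!nrow(pix))
    return(list(center_xy = c(NA_real_, NA_real_), nose_xy = c(NA_real_, NA_real_),
                tail_xy = c(NA_real_, NA_real_), elongation_pct = NA_real_,
                body_angle_deg = NA_real_))
  x <- (pix[, "col"] - 0.5) / px_per_cm
  y <- (pix[, "row"] - 0.5) / px_per_cm
  ctr <- c(mean(x), mean(y))
  xc <- x - ctr[1]; yc <- y - ctr[2]
  cv <- matrix(c(mean(xc^2), mean(xc * yc), mean(xc * yc), mean(yc^2)), 2)
  eg <- eigen(cv, symmetric = TRUE)
  axis <- eg$vectors[, 1]
  elong <- 100 * (1 - sqrt(max(0, eg$values[2]) / max(eg$values[1], 1e-12)))
  proj <- xc * axis[1] + yc * axis[2]
  # spine walk: bin pixels by axis projection, follow bin centroids, and
  # extrapolate half a bin beyond the end centroids to reach the body tips;
  # this stays on the body even for bent postures
  nb <- 12L
  br <- range(proj)
  bin <- if (diff(br) < 1e-9) rep(1L, length(proj))
         else pmin(nb, 1L + floor((proj - br[1]) / diff(br) * nb))
  bx <- tapply(x, bin, mean); by <- tapply(y, bin, mean)
  spine <- cbind(as.numeric(bx), as.numeric(by))
  ns <- nrow(spine)
  endA <- if (ns >= 2) spine[1, ] + 0.5 * (spine[1, ] - spine[2, ]) else spine[1, ]
  endB <- if (ns >= 2) spine[ns, ] + 0.5 * (spine[ns, ] - spine[ns - 1, ]) else spine[ns, ]
  bright <- function(p) {
    d2tip <- (x - p[1])^2 + (y - p[2])^2
    sel <- d2tip <= 0.36  # within 0.6 cm of the tip
    if (!any(sel)) sel <- which.min(d2tip)
    mean(intensity[pix[sel, , drop = FALSE]])
  }
  if (bright(endA) >= bright(endB)) { nose <- endA; tail_end <- endB }
  else { nose <- endB; tail_end <- endA }
  tail_base <- tail_end + 0.15 * (ctr - tail_end)
  list(center_xy = ctr, nose_xy = nose, tail_xy = tail_base,
       elongation_pct = max(0, min(100, elong)),
       body_angle_deg = included_deviation_deg(ctr, nose, tail_base))
}

# deviation from collinearity at the center: 180 deg minus the angle between
# the center->nose and center->tail vectors
included_deviation_deg <- function(center, nose, tail) {
  a <- nose - center; b <- tail - center
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-9 || nb < 1e-9) return(0)
  inc <- acos(max(-1, min(1, sum(a * b) / (na * nb)))) * 180 / pi
  180 - inc
}

#' Track a frame stack
#'
#' Runs background estimation, per-frame segmentation and body-point
#' extraction over a frame stack, stabilizes head/tail identity across frames
#' by nearest-neighbor continuity, and returns a [tracking_series()] in cm
#' together with the pixel-change mobility signal (percentage of body-mask
#' pixels, union-normalized, that changed between consecutive frames) as
#' attribute `"mobility"`. Frames where segmentation fails become missing
#' samples.
#'
#' @param frames Anything accepted by [frame_source()].
#' @param px_per_cm Spatial calibration.
#' @param sample_rate_hz Acquisition rate of the stack.
#' @param session_id Identifier for the resulting series.
#' @param background Optional pre-computed background; estimated if `NULL`.
#' @param thr Optional fixed segmentation threshold (default per-frame Otsu).
#' @param verbose Log per-frame failures.
#' @return A `tracking_series` with attribute `"mobility"` (a
#'   [track_signal()], %).
#' @export
track_video <- function(frames, px_per_cm, sample_rate_hz,
                        session_id = "tracked", background = NULL, thr = NULL,
                        verbose = FALSE) {
  src <- frame_source(frames)
  n <- src$n
  if (is.null(background)) background <- estimate_background(frames)
  ny <- nrow(background); nx <- ncol(background)
  center <- matrix(NA_real_, n, 2); nose <- matrix(NA_real_, n, 2)
  tail <- matrix(NA_real_, n, 2)
  elong <- rep(NA_real_, n); ang <- rep(NA_real_, n)
  mob <- numeric(n)
  prev_mask <- NULL
  prev_nose <- NULL; prev_tail <- NULL
  n_fail <- 0L
  for (i in seq_len(n)) {
    fr <- src$get(i)
    mask <- segment_frame(fr, background, thr = thr)
    if (!any(mask)) {
      n_fail <- n_fail + 1L
      if (verbose) message(sprintf("frame %d: segmentation failed", i))
      mob[i] <- if (is.null(prev_mask)) 0 else 100
      prev_mask <- NULL
      next
    }
    bp <- extract_body_points(mask, fr, px_per_cm)
    # head/tail continuity: keep the orientation closest to the previous frame
    if (!is.null(prev_nose)) {
      body_len <- sqrt(sum((bp$nose_xy - bp$tail_xy)^2)) / 0.85
      jump <- sqrt(sum((bp$center_xy - prev_ctr)^2))
      if (jump < body_len) {
        keep <- sum((bp$nose_xy - prev_nose)^2) + sum((bp$tail_xy - prev_tail)^2)
        swap <- sum((bp$nose_xy - prev_tail)^2) + sum((bp$tail_xy - prev_nose)^2)
        if (swap < keep) {
          tip <- bp$nose_xy
          # un-pull the tail-base to the raw end before re-pulling on the other side
          raw_tail <- (bp$tail_xy - 0.15 * bp$center_xy) / 0.85
          bp$nose_xy <- raw_tail
          bp$tail_xy <- tip + 0.15 * (bp$center_xy - tip)
        }
      }
    }
    center[i, ] <- bp$center_xy; nose[i, ] <- bp$nose_xy; tail[i, ] <- bp$tail_xy
    elong[i] <- bp$elongation_pct; ang[i] <- bp$body_angle_deg
    ang[i] <- included_deviation_deg(bp$center_xy, bp$nose_xy, bp$tail_xy)
    prev_nose <- bp$nose_xy; prev_tail <- bp$tail_xy; prev_ctr <- bp$center_xy
    if (i > 1L) {
      if (is.null(prev_mask)) mob[i] <- 100
      else {
        uni <- sum(mask | prev_mask)
        mob[i] <- if (uni == 0) 0 else 100 * sum(xor(mask, prev_mask)) / uni
      }
    }
    prev_mask <- mask
  }
  if (n_fail > 0)
    message(sprintf("track_video: %d of %d frames failed segmentation and are missing", n_fail, n))
  series <- tracking_series(
    session_id = session_id, sample_rate_hz = sample_rate_hz,
    t = (seq_len(n) - 1L) / sample_rate_hz,
    center = center, nose = nose, tail = tail,
    elongation_pct = elong, body_angle_deg = ang,
    missing = is.na(center[, 1]),
    arena_w_cm = nx / px_per_cm, arena_h_cm = ny / px_per_cm)
  attr(series, "mobility") <- track_signal(mob, "%", sample_rate_hz)
  series
}
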