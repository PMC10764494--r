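#' Render a tracking series to overhead frames
#'
#' Produces one 8-bit grayscale frame per sample, emulating the overhead
#' infra-red camera view the tracker module consumes: dark background, bright
#' mouse-like blob. The blob is a chain of disks along a quadratic spine from
#' tail-base to nose whose control point is chosen so the blob centroid
#' coincides with the series center-point; its width encodes body elongation
#' (`elongation = 100 * (1 - width/length)`), its end-to-end bend encodes the
#' body angle, and the nose end is brighter so the tracker can orient
#' head/tail. Missing samples render as background-only frames.
#'
#' @param series A [tracking_series()].
#' @param px_per_cm Spatial calibration, pixels per cm.
#' @param out_dir Output directory for `frame_%06d.png` files; created if
#'   needed. If `NULL`, frames are returned in memory as a list of matrices
#'   (rows = y, columns = x, values in \[0, 1\]).
#' @param body_intensity,nose_intensity,background Gray levels in \[0, 1\].
#' @param n_disks Number of disks along the spine.
#' @return File paths (invisibly) when writing, else the list of matrices.
#' @export
render_frames <- function(series, px_per_cm, out_dir = NULL,
                          body_intensity = 0.78, nose_intensity = 0.98,
                          background = 0.08, n_disks = 21L) {
  nx <- as.integer(round(series$arena_w_cm * px_per_cm))
  ny <- as.integer(round(series$arena_h_cm * px_per_cm))
  n <- length(series$t)
  writing <- !is.null(out_dir)
  if (writing) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop(sprintf("cannot create directory '%s'", out_dir))
    paths <- file.path(out_dir, sprintf("frame_%06d.png", seq_len(n)))
  } else frames <- vector("list", n)
  bg <- matrix(background, ny, nx)
  tseq <- seq(0, 1, length.out = n_disks)
  for (i in seq_len(n)) {
    img <- bg
    if (!series$missing[i]) {
      img <- draw_mouse(bg, series$center[i, ], series$nose[i, ], series$tail[i, ],
                        series$elongation_pct[i], px_per_cm, tseq,
                        body_intensity, nose_intensity)
    }
    if (writing) png::writePNG(img, paths[i]) else frames[[i]] <- img
  }
  if (writing) invisible(paths) else frames
}

draw_mouse <- function(img, C, N, T, elong, px, tseq, body_val, nose_val) {
  ny <- nrow(img); nx <- ncol(img)
  # quadratic spine through tail and nose with mean at the center-point,
  # resampled to equal arc length so blob mass is uniform along the body
  P1 <- 3 * C - N - T
  td <- seq(0, 1, length.out = 60)
  bd <- outer((1 - td)^2, T) + outer(2 * td * (1 - td), P1) + outer(td^2, N)
  arc <- c(0, cumsum(sqrt(rowSums(diff(bd)^2))))
  at <- stats::approx(arc, td, xout = seq(0, arc[length(arc)],
                                          length.out = length(tseq)))$y
  b <- outer((1 - at)^2, T) + outer(2 * at * (1 - at), P1) + outer(at^2, N)
  b <- b + matrix(C - colMeans(b), nrow(b), 2, byrow = TRUE)
  # body width chosen so the blob's second-moment axis ratio encodes the
  # elongation even for a bent spine, using a capsule mass model: a uniform
  # band of half-width r swept along the spine plus half-disk end caps
  rho <- max(0.03, 1 - elong / 100)
  ctr <- colMeans(b)
  bc <- sweep(b, 2, ctr)
  cv <- crossprod(bc) / nrow(b)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  s_arc <- arc[length(arc)]
  L <- 2 * sqrt(3 * max(ev[1], 1e-9))    # equivalent uniform spine length
  f <- function(r) {
    m1 <- 2 * r * s_arc; m2 <- pi * r^2
    cc <- 4 * r / (3 * pi)
    cap_x2 <- (L / 2 + cc)^2 + r^2 / 4 - cc^2
    V1 <- (m1 * ev[1] + m2 * cap_x2) / (m1 + m2)
    V2 <- (m1 * (ev[2] + r^2 / 3) + m2 * (ev[2] + r^2 / 4)) / (m1 + m2)
    V2 - rho^2 * V1
  }
  r_lo <- 0.22; r_hi <- max(s_arc / 2, r_lo + 0.01)
  r_cm <- if (f(r_lo) >= 0) r_lo
          else if (f(r_hi) <= 0) r_hi
          else stats::uniroot(f, c(r_lo, r_hi), tol = 1e-4)$root
  pad <- r_cm + 2 / px
  c0 <- max(1L, floor((min(b[, 1]) - pad) * px)); c1 <- min(nx, ceiling((max(b[, 1]) + pad) * px))
  r0 <- max(1L, floor((min(b[, 2]) - pad) * px)); r1 <- min(ny, ceiling((max(b[, 2]) + pad) * px))
  if (c1 < c0 || r1 < r0) return(img)
  xs <- (c0:c1 - 0.5) / px
  ys <- (r0:r1 - 0.5) / px
  npx <- length(xs); npy <- length(ys)
  dx <- outer(rep(xs, each = npy), b[, 1], "-")
  dy <- outer(rep(ys, times = npx), b[, 2], "-")
  d2 <- dx^2 + dy^2
  dmin <- sqrt(matrixStats_rowMins(d2))
  nearest <- max.col(-d2, ties.method = "first")
  # only the terminal nose disk is brighter: enough to orient head/tail but
  # too little mass to bias the centroid through threshold dilation
  val <- ifelse(nearest == length(tseq), nose_val, body_val)
  alpha <- pmin(1, pmax(0, (r_cm - dmin) * px + 0.5))
  patch <- img[r0:r1, c0:c1]
  patch <- patch + alpha * (val - patch)
  img[r0:r1, c0:c1] <- patch
  img
}

# row-wise minimum of a matrix without extra dependencies
matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

#' Empty-arena background frame
#'
#' The frame the camera sees before the animal is placed in the arena, at the
#' same calibration and gray level as [render_frames()] output. Supplying it
#' to [track_video()] mirrors the standard background-capture step of a
#' tracking experiment and is the reliable choice for sessions where the
#' animal rests in one spot for long periods (a sleeping mouse contaminates
#' any background estimated from the occupied frames themselves; see
#' [estimate_background()]).
#'
#' @inheritParams render_frames
#' @return A background matrix.
#' @export
render_background <- function(series, px_per_cm, background = 0.08) {
  matrix(background,
         as.integer(round(series$arena_h_cm * px_per_cm)),
         as.integer(round(series$arena_w_cm * px_per_cm)))
}

#' Write frames as a multi-page TIFF
#'
#' Convenience wrapper around [render_frames()] for the multi-page TIFF
#' interchange format (requires the `tiff` package).
#'
#' @inheritParams render_frames
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
render_frames_tiff <- function(series, px_per_cm, path, ...) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for multi-page TIFF output")
  frames <- render_frames(series, px_per_cm, out_dir = NULL, ...)
  tiff::writeTIFF(frames, path, bits.per.sample = 8L)
  invisible(path)
}
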