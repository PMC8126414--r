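# exact distance from pixel centres to a polyline, with the local tube
# width interpolated along the arc; returns the rendered mask
render_tube <- function(nrow_px, ncol_px, pts, widths_um, pixel_size) {
  # pixel centres in um, 0-based (row, col), y-down
  rr <- (seq_len(nrow_px) - 0.5) * pixel_size
  cc <- (seq_len(ncol_px) - 0.5) * pixel_size
  P <- cbind(rep(rr, times = ncol_px), rep(cc, each = nrow_px))
  ns <- nrow(pts) - 1L
  best_d <- rep(Inf, nrow(P))
  best_w <- rep(widths_um[1], nrow(P))
  for (i in seq_len(ns)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 > 0) {
      pmin(1, pmax(0, ((P[, 1] - a[1]) * ab[1] + (P[, 2] - a[2]) * ab[2]) / len2))
    } else 0
    dx <- P[, 1] - (a[1] + t * ab[1])
    dy <- P[, 2] - (a[2] + t * ab[2])
    d <- sqrt(dx * dx + dy * dy)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    wseg <- widths_um[i] + t * (widths_um[i + 1L] - widths_um[i])
    best_w[upd] <- wseg[upd]
  }
  matrix(best_d <= best_w / 2, nrow_px, ncol_px)
}

polyline_length <- function(pts) sum(sqrt(rowSums(diff(pts)^2)))

#' Synthetic growing-tube image series with ground truth
#'
#' Renders a gently curved epithelial tube as a thick polyline on a pixel
#' grid, growing in length and changing in width over the frames
#' (geometric interpolation from 1 to the stated total factors), with an
#' optional side branch appearing halfway through the series. Masks are
#' exact-distance renderings thresholded at the half-width, so measured
#' widths are unbiased to sub-pixel level. Ground truth carries the exact
#' per-frame centerline lengths and widths.
#'
#' @param length0 Initial centerline length (µm).
#' @param width0 Initial tube width (µm); must be >= 4 px.
#' @param length_growth,width_growth Total growth factors reached at the
#'   final frame.
#' @param n_frames Number of frames (>= 2).
#' @param branching Add a side branch from the midpoint of the tube from
#'   frame `ceiling(n_frames/2)` on.
#' @param pixel_size µm/px.
#' @param noise SD of Gaussian pixel noise for the grayscale rendering
#'   (`images`); the masks are always noise-free.
#' @param seed RNG seed (used for the noise).
#' @param curvature Amplitude of the tube's bow as a fraction of its
#'   length.
#' @return List of class `tube_series`: `masks` (list of logical matrices),
#'   `images` (grayscale, foreground 0.85 on background 0.15 plus noise),
#'   `pixel_size`, and `ground_truth` (per-frame `length_um`, `width_um`,
#'   relative factors, branch metadata).
#' @export
make_tube_image_series <- function(length0 = 60, width0 = 12,
                                   length_growth = 2, width_growth = 0.8,
                                   n_frames = 5, branching = FALSE,
                                   pixel_size = 1, noise = 0, seed = 1,
                                   curvature = 0.08) {
  stopifnot(n_frames >= 2, length0 > 0, width0 > 0)
  if (width0 * min(1, width_growth) / pixel_size < 4) {
    stop("tube width must stay >= 4 px; increase width0 or resolution")
  }
  set.seed(seed)
  lf <- length_growth^((seq_len(n_frames) - 1) / (n_frames - 1))
  wf <- width_growth^((seq_len(n_frames) - 1) / (n_frames - 1))
  Lmax <- length0 * max(lf)
  Wmax <- width0 * max(wf)
  margin <- Wmax + 6 * pixel_size
  ncol_px <- ceiling((Lmax + 2 * margin) / pixel_size)
  nrow_px <- ceiling((2 * curvature * Lmax + 2 * margin +
                        (if (branching) 0.45 * Lmax else 0)) / pixel_size)
  y0 <- (nrow_px * pixel_size) * (if (branching) 0.30 else 0.5)

  masks <- list(); images <- list()
  gt_len <- gt_wid <- numeric(n_frames)
  gt_branch_len <- rep(NA_real_, n_frames)
  branch_start <- ceiling(n_frames / 2)

  for (f in seq_len(n_frames)) {
    L <- length0 * lf[f]
    W <- width0 * wf[f]
    s <- seq(0, 1, length.out = 80)
    pts <- cbind(y0 + curvature * L * sin(pi * s),   # row (y), bowed
                 margin + L * s)                      # col (x)
    if (max(pts[, 2]) + W / 2 + 2 > ncol_px * pixel_size ||
        max(pts[, 1]) + W / 2 + 2 > nrow_px * pixel_size) {
      stop("tube leaves the canvas; increase the canvas or reduce growth")
    }
    m <- render_tube(nrow_px, ncol_px, pts, rep(W, nrow(pts)), pixel_size)
    gt_len[f] <- polyline_length(pts)
    gt_wid[f] <- W
    if (branching && f >= branch_start) {
      frac <- (f - branch_start + 1) / (n_frames - branch_start + 1)
      bl <- 0.35 * L * frac
      base <- pts[40, ]
      sb <- seq(0, 1, length.out = 40)
      bpts <- cbind(base[1] + bl * sb * 0.9, base[2] + bl * sb * 0.45)
      m <- m | render_tube(nrow_px, ncol_px, bpts, rep(W * 0.8, nrow(bpts)),
                           pixel_size)
      gt_branch_len[f] <- polyline_length(bpts)
    }
    img <- matrix(0.15, nrow_px, ncol_px)
    img[m] <- 0.85
    if (noise > 0) img <- img + matrix(stats::rnorm(length(img), 0, noise),
                                       nrow_px, ncol_px)
    masks[[f]] <- m
    images[[f]] <- img
  }
  structure(list(
    masks = masks, images = images, pixel_size = pixel_size,
    ground_truth = list(length_um = gt_len, width_um = gt_wid,
                        rel_length = gt_len / gt_len[1],
                        rel_width = gt_wid / gt_wid[1],
                        branch_length_um = gt_branch_len,
                        branch_start_frame = if (branching) branch_start else NA,
                        seed = seed)
  ), class = "tube_series")
}

#' Write / read a tube series as multi-frame TIFF
#'
#' @param series A [make_tube_image_series()] result.
#' @param path Output TIFF path.
#' @param what `"images"` (grayscale) or `"masks"`.
#' @return `write_tube_series` invisibly returns `path`;
#'   `read_tube_series` returns a list of matrices.
#' @export
write_tube_series <- function(series, path, what = c("images", "masks")) {
  what <- match.arg(what)
  frames <- series[[what]]
  arr <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]),
                          length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- pmin(1, pmax(0, frames[[i]] * 1))
  EBImage::writeImage(EBImage::Image(aperm(arr, c(2, 1, 3))), path,
                      type = "tiff")
  invisible(path)
}

#' @rdname write_tube_series
#' @param path TIFF path to read.
#' @export
read_tube_series <- function(path) {
  img <- EBImage::readImage(path)
  arr <- EBImage::imageData(img)
  if (length(dim(arr)) == 2) arr <- array(arr, dim = c(dim(arr), 1))
  lapply(seq_len(dim(arr)[3]), function(i) t(arr[, , i]))
}
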