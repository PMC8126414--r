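#' Binary explant frame
#'
#' A single time point of a segmented 2D explant: a boolean mask with its
#' pixel size. Only the largest foreground component is kept; the number of
#' discarded small objects is recorded.
#'
#' @param mask Logical (or 0/1) matrix, row/col indexed, y-down.
#' @param pixel_size Pixel edge length (µm/px).
#' @param timestamp Acquisition time (arbitrary units, optional).
#' @param min_object_px Objects smaller than this are discarded before the
#'   dominant component is selected.
#' @return Object of class `binary_frame`.
#' @export
binary_frame <- function(mask, pixel_size = 1, timestamp = NA_real_,
                         min_object_px = 16) {
  mask <- mask > 0
  if (!any(mask)) stop("empty foreground mask")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  discarded <- sum(sizes > 0) - 1L
  structure(list(mask = lab == keep, pixel_size = pixel_size,
                 timestamp = timestamp, n_discarded = discarded),
            class = "binary_frame")
}

#' @export
print.binary_frame <- function(x, ...) {
  cat(sprintf("Binary frame %dx%d px (%.3g um/px), %d fg px, %d object(s) discarded\n",
              nrow(x$mask), ncol(x$mask), x$pixel_size, sum(x$mask),
              x$n_discarded))
  invisible(x)
}

#' Segment a grayscale explant image
#'
#' The segmentation chain used for 2D explant movies: local contrast
#' enhancement (CLAHE), background subtraction by grayscale opening with a
#' disc (rolling-ball-style background estimate), global Otsu thresholding,
#' Gaussian smoothing of the binary boundary and re-thresholding at 0.5.
#' All parameters are package defaults, logged in the returned object.
#'
#' @param img Numeric matrix (any range; normalized internally).
#' @param pixel_size µm/px.
#' @param params List: `clahe_nx` (tiles per side, 0 disables), `bg_radius`
#'   (background disc radius, px; 0 disables), `blur_sigma` (boundary
#'   smoothing, px), `invert` (segment dark-on-bright input).
#' @param timestamp Passed to [binary_frame()].
#' @return A [binary_frame()] with a `params` attribute recording the chain.
#' @export
preprocess <- function(img, pixel_size = 1,
                       params = list(clahe_nx = 8, bg_radius = 25,
                                     blur_sigma = 2, invert = FALSE),
                       timestamp = NA_real_) {
  stopifnot(is.matrix(img), is.numeric(img))
  defaults <- list(clahe_nx = 8, bg_radius = 25, blur_sigma = 2,
                   invert = FALSE)
  params <- utils::modifyList(defaults, params)
  rng <- range(img)
  if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  if (isTRUE(params$invert)) img <- 1 - img
  x <- EBImage::Image(img)
  if (params$clahe_nx > 0) {
    x <- tryCatch(EBImage::clahe(x, nx = params$clahe_nx),
                  error = function(e) x)
  }
  if (params$bg_radius > 0) {
    brush <- EBImage::makeBrush(2 * params$bg_radius + 1, shape = "disc")
    bg <- EBImage::opening(x, brush)
    x <- x - bg
  }
  if (diff(range(x)) > 0) x <- EBImage::normalize(x)
  thr <- EBImage::otsu(x)
  bin <- x > thr
  if (params$blur_sigma > 0) {
    sm <- EBImage::gblur(EBImage::Image(bin * 1), sigma = params$blur_sigma)
    bin <- sm > 0.5
  }
  m <- matrix(as.logical(bin), nrow = nrow(img), ncol = ncol(img))
  if (!any(m)) stop("empty foreground after segmentation")
  fr <- binary_frame(m, pixel_size, timestamp)
  fr$params <- params
  fr
}
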