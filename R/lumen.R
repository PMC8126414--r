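#' Synthetic lumen cross-section polygons
#'
#' Generates idealized lumen cross-section geometries: ellipses (open or
#' collapsed, slit-like lumens) and dumbbells (the post-collapse morphology
#' in which two open lobes remain connected by a narrow waist).
#'
#' The dumbbell is an ellipse modulated along x so that the half-width at
#' the centre is `waist_fraction` times the elliptical half-width, leaving
#' two width maxima either side of the waist.
#'
#' @param kind `"ellipse"` or `"dumbbell"`.
#' @param a Semi-major axis (µm, along x).
#' @param b Semi-minor axis (µm, along y). `a >= b > 0`.
#' @param n_vertices Number of polygon vertices (default 512).
#' @param waist_fraction For dumbbells: central half-width as a fraction of
#'   the elliptical half-width, in (0, 1].
#' @return A [cross_section()] polygon (counter-clockwise).
#' @examples
#' ell <- make_lumen_polygon("ellipse", a = 20, b = 1)  # 2 um collapsed lumen
#' db <- make_lumen_polygon("dumbbell", a = 20, b = 5, waist_fraction = 0.3)
#' @export
make_lumen_polygon <- function(kind = c("ellipse", "dumbbell"), a, b,
                               n_vertices = 512, waist_fraction = 0.5) {
  kind <- match.arg(kind)
  stopifnot(a >= b, b > 0, n_vertices >= 16)
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  x <- a * cos(theta)
  y <- b * sin(theta)
  if (kind == "dumbbell") {
    if (!(waist_fraction > 0 && waist_fraction <= 1)) {
      stop("waist_fraction must be in (0, 1]")
    }
    # smooth pinch centred at x = 0, of width ~a/2
    pinch <- 1 - (1 - waist_fraction) * exp(-(x / (a / 3))^2)
    y <- y * pinch
  }
  cross_section(cbind(x, y))
}
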