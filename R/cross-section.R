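#' Polygonal lumen cross-section
#'
#' A simple, counter-clockwise closed polygon describing a lumen
#' cross-section, vertices in micrometres. The constructor enforces
#' orientation and rejects self-intersecting or degenerate input.
#'
#' @param xy Two-column numeric matrix of vertices (µm), implicitly closed.
#' @return An object of class `cross_section` (a matrix with attributes).
#' @export
cross_section <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2 || nrow(xy) < 3 || !is.numeric(xy) || anyNA(xy)) {
    stop("'xy' must be a numeric n x 2 matrix, n >= 3, no NAs")
  }
  # drop duplicated closing vertex
  if (all(xy[1, ] == xy[nrow(xy), ])) xy <- xy[-nrow(xy), , drop = FALSE]
  a <- polygon_area(xy)
  if (abs(a) < 1e-12) stop("polygon has (near-)zero area")
  if (a < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]  # enforce CCW
  if (!is_simple_polygon(xy)) stop("polygon is self-intersecting")
  structure(xy, class = c("cross_section", "matrix"), units = "um")
}

# Shoelace signed area; positive for CCW.
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- 0.5 * sum(cr)
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

polygon_perimeter <- function(xy) {
  d <- xy[c(2:nrow(xy), 1), , drop = FALSE] - xy
  sum(sqrt(rowSums(d^2)))
}

# O(n^2) segment-intersection test; adequate for the polygon sizes used here.
is_simple_polygon <- function(xy) {
  n <- nrow(xy)
  if (n > 2000) return(TRUE)  # constructor-level check skipped for dense traces
  p1 <- xy
  p2 <- xy[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # skip edges adjacent to edge i
    if (!length(js)) next
    if (any(segments_intersect(p1[i, ], p2[i, ], p1[js, , drop = FALSE],
                               p2[js, , drop = FALSE]))) {
      return(FALSE)
    }
  }
  TRUE
}

# vectorized proper-intersection test of segment (a1,a2) against rows of (b1,b2)
segments_intersect <- function(a1, a2, b1, b2) {
  d1 <- cross2(a2 - a1, t(t(b1) - a1))
  d2 <- cross2(a2 - a1, t(t(b2) - a1))
  d3 <- cross2_rows(b2 - b1, -sweep(b1, 2, a1))
  d4 <- cross2_rows(b2 - b1, -sweep(b1, 2, a2))
  (d1 * d2 < 0) & (d3 * d4 < 0)
}
cross2 <- function(v, m) v[1] * m[, 2] - v[2] * m[, 1]
cross2_rows <- function(m1, m2) m1[, 1] * m2[, 2] - m1[, 2] * m2[, 1]

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("Lumen cross-section polygon: %d vertices, area %.4g um^2, perimeter %.4g um\n",
              nrow(x), polygon_area(unclass(x)), polygon_perimeter(unclass(x))))
  invisible(x)
}

#' Rescale a cross-section along one axis
#'
#' Scales the polygon coordinates along a named axis about the section
#' centroid, leaving the other axis untouched. This emulates the numerical
#' narrowing of a segmented lumen geometry from its subapically resolved
#' opening down to the true luminal width.
#'
#' @param section A [cross_section()].
#' @param factor Positive scale factor.
#' @param axis `"x"` or `"y"`: the axis whose coordinates are scaled.
#' @return The rescaled [cross_section()].
#' @examples
#' ell <- make_lumen_polygon("ellipse", a = 20, b = 10)
#' narrow <- rescale_section(ell, 0.1, axis = "y")   # 20 um -> 2 um opening
#' @export
rescale_section <- function(section, factor, axis = c("y", "x")) {
  stopifnot(inherits(section, "cross_section"), is.numeric(factor),
            length(factor) == 1, factor > 0)
  axis <- match.arg(axis)
  xy <- unclass(section)
  ctr <- polygon_centroid(xy)
  j <- if (axis == "x") 1L else 2L
  xy[, j] <- ctr[j] + factor * (xy[, j] - ctr[j])
  if (abs(polygon_area(xy)) < 1e-9) stop("rescaled polygon is degenerate")
  cross_section(xy)
}

#' Read / write cross-section polygons
#'
#' CSV files have two columns `x`, `y` in micrometres; `.json` files hold a
#' GeoJSON-style Polygon geometry (`type`, `coordinates` with a closed outer
#' ring). The format is chosen by the file extension.
#' @param path File path (`.csv` or `.json`).
#' @return `read_section` returns a [cross_section()]; `write_section`
#'   invisibly returns `path`.
#' @export
read_section <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(obj$type, "Polygon")) stop("expected a GeoJSON Polygon")
    ring <- obj$coordinates[1, , ]
    return(cross_section(ring))
  }
  df <- utils::read.csv(path)
  cross_section(cbind(df$x, df$y))
}

#' @rdname read_section
#' @param section A [cross_section()].
#' @export
write_section <- function(section, path) {
  if (grepl("\\.json$", path)) {
    ring <- rbind(unclass(section), unclass(section)[1, ])  # closed ring
    jsonlite::write_json(
      list(type = "Polygon",
           coordinates = array(ring, dim = c(1, nrow(ring), 2))),
      path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  utils::write.csv(data.frame(x = section[, 1], y = section[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}
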