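#' Outgrowth bias of a trajectory
#'
#' Elongation bias of the simulated tissue:
#' \deqn{bias = \frac{L_f / L_0}{W_f / W_0},}
#' with \eqn{L} the tissue extent along the longitudinal (force, y) axis and
#' \eqn{W} the transverse extent, both measured from the bounding box of
#' cell centroids (less sensitive to single-cell boundary protrusions than
#' the vertex bounding box). A value of 1 is isotropic growth; 2 means the
#' tissue lengthened twice as much as it widened.
#'
#' @param trajectory A `vm_trajectory` or a list of at least two snapshots
#'   (each with a `cells` data frame holding centroid columns `x`, `y`).
#' @return Bias (dimensionless).
#' @export
compute_outgrowth_bias <- function(trajectory) {
  snaps <- if (inherits(trajectory, "vm_trajectory")) trajectory$snapshots
  else trajectory
  if (length(snaps) < 2) stop("need at least 2 snapshots")
  ext <- function(s) {
    c(W = diff(range(s$cells$x)), L = diff(range(s$cells$y)))
  }
  e0 <- ext(snaps[[1]])
  ef <- ext(snaps[[length(snaps)]])
  if (any(e0 == 0)) stop("zero initial extent")
  unname((ef["L"] / e0["L"]) / (ef["W"] / e0["W"]))
}

#' Division-angle histogram
#'
#' Normalized histogram of cell division angles on \[0, 90\] degrees
#' (0 = division axis along the longitudinal axis).
#'
#' @param records Division-record data frame (column `division_angle`).
#' @param bin_width_deg Bin width in degrees; must divide 90.
#' @return Named numeric vector of fractions (sums to 1); names are bin
#'   centres.
#' @export
division_angle_histogram <- function(records, bin_width_deg = 15) {
  if (!nrow(records)) stop("no division records")
  if (90 %% bin_width_deg != 0) stop("90 must be divisible by bin width")
  brk <- seq(0, 90, by = bin_width_deg)
  h <- graphics::hist(pmin(records$division_angle, 90 - 1e-9), breaks = brk,
                      plot = FALSE)
  out <- h$counts / sum(h$counts)
  names(out) <- (brk[-length(brk)] + brk[-1]) / 2
  out
}

#' Cell-shape statistics of a mesh
#'
#' Apical area coefficient of variation (population SD over mean) and the
#' polygon-class (neighbour-count) histogram. The neighbour count of a cell
#' is the number of cells sharing at least one edge with it; cells owning a
#' free boundary edge are included and flagged.
#'
#' @param mesh A [tissue_mesh()].
#' @return List with `area_cv`, `polygon_class_histogram` (named fractions,
#'   sums to 1), `neighbours` (per-cell data frame with a boundary flag),
#'   and `aspect_ratios` (per-cell principal-axis aspect ratio).
#' @export
shape_statistics <- function(mesh) {
  A <- cell_areas(mesh)
  n <- length(A)
  cv <- stats::sd(A) * sqrt((n - 1) / n) / mean(A)
  nb <- mesh_neighbours(mesh)
  tab <- table(factor(nb$n_neighbours, levels = 0:max(9, nb$n_neighbours)))
  hist <- as.numeric(tab) / n
  names(hist) <- names(tab)
  ar <- vapply(mesh$cells, function(cl) {
    eg <- eigen(polygon_covariance(mesh$vertices[cl, , drop = FALSE]),
                symmetric = TRUE, only.values = TRUE)$values
    sqrt(max(eg[1], 0) / max(eg[2], 1e-300))
  }, numeric(1))
  list(area_cv = cv, polygon_class_histogram = hist[hist > 0 | names(hist) == "6"],
       neighbours = nb, aspect_ratios = ar)
}

#' Relative axial displacement profile
#'
#' For each initial cell, the displacement of its descendants' mean centroid
#' along the longitudinal axis between the first and last snapshot,
#' normalized by the maximum absolute axial displacement, as a function of
#' the cell's initial axial position. A uniformly strained tissue gives a
#' linear profile.
#'
#' @param trajectory A `vm_trajectory` (or snapshot list with `origin`
#'   columns).
#' @return Data frame (`origin`, `y0`, `displacement`, `rel_displacement`),
#'   sorted by initial axial position.
#' @export
displacement_profile <- function(trajectory) {
  snaps <- if (inherits(trajectory, "vm_trajectory")) trajectory$snapshots
  else trajectory
  if (length(snaps) < 2) stop("need at least 2 snapshots")
  s0 <- snaps[[1]]$cells
  sf <- snaps[[length(snaps)]]$cells
  yf <- tapply(sf$y, sf$origin, mean)
  y0 <- s0$y[match(as.integer(names(yf)), s0$origin)]
  keep <- !is.na(y0)
  d <- as.numeric(yf)[keep] - y0[keep]
  rel <- d / max(abs(d))
  out <- data.frame(origin = as.integer(names(yf))[keep], y0 = y0[keep],
                    displacement = d, rel_displacement = rel)
  out[order(out$y0), ]
}
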