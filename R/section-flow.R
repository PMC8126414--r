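#' Fully developed laminar flow in an arbitrary lumen cross-section
#'
#' Solves the axial-flow Poisson problem \eqn{-\nabla^2 u = G/\mu} on the
#' interior of a simple polygon with no-slip walls (\eqn{u = 0} on the
#' boundary), the fully developed limit of Stokes flow along a prismatic
#' tube. The pressure gradient \eqn{G} is then rescaled exactly (the problem
#' is linear) so that the cross-section mean velocity or the flow rate
#' matches the [flow_spec()]. Wall shear stress is the viscosity times the
#' one-sided normal derivative of \eqn{u} at the wall, obtained by a
#' quadratic (in wall distance) least-squares extrapolation of near-wall
#' interior samples.
#'
#' The discretization is a regular-grid masked finite-difference scheme with
#' sub-cell boundary correction (Shortley-Weller stencils), so the no-slip
#' boundary is honoured at its exact location rather than at the nearest
#' grid node.
#'
#' @param section A [cross_section()] polygon (µm).
#' @param spec A [flow_spec()].
#' @param resolution Number of grid cells across the larger bounding-box
#'   extent. Default 400.
#' @return An object of class `flow_solution`: list with `grid` (x, y node
#'   coordinate vectors), `u` (velocity matrix, µm/s, NA outside), `boundary`
#'   (data.frame: arc_length, x, y, tau), `tau_mean`, `tau_max`, `tau_min`
#'   (arc-length weighted stats, Pa), `mean_velocity`, `flow_rate`,
#'   `pressure_gradient` (Pa/µm), `h` (grid spacing).
#' @examples
#' \donttest{
#' sec <- make_lumen_polygon("ellipse", a = 20, b = 2, n_vertices = 512)
#' sol <- solve_cross_section_flow(sec, flow_spec(), resolution = 200)
#' sol$tau_mean
#' }
#' @export
solve_cross_section_flow <- function(section, spec = flow_spec(), resolution = 400) {
  stopifnot(inherits(section, "cross_section"), inherits(spec, "flow_spec"))
  poly <- unclass(section)
  mu <- spec$viscosity
  area <- polygon_area(poly)

  bb <- apply(poly, 2, range)
  ext <- bb[2, ] - bb[1, ]
  h <- max(ext) / resolution
  xg <- seq(bb[1, 1] + h / 2, bb[2, 1] - h / 4, by = h)
  yg <- seq(bb[1, 2] + h / 2, bb[2, 2] - h / 4, by = h)
  nx <- length(xg); ny <- length(yg)

  pts <- cbind(rep(xg, times = ny), rep(yg, each = nx))
  inside <- points_in_polygon(pts, poly)
  idx <- which(inside)
  if (length(idx) < 9) stop("section too thin for this resolution; increase 'resolution'")

  # exact distance to the polygon boundary for interior nodes (used both for
  # the resolution check and the near-wall shear fit)
  dwall <- rep(NA_real_, nx * ny)
  dwall[idx] <- dist_to_polygon(pts[idx, , drop = FALSE], poly)
  if (2 * max(dwall, na.rm = TRUE) / h < 20) {
    stop("fewer than 20 interior samples across the narrowest opening; ",
         "increase 'resolution'")
  }

  sol <- sw_poisson_solve(pts, inside, nx, ny, h, poly)
  u <- rep(NA_real_, nx * ny)
  u[idx] <- sol  # solution of -lap u = 1

  # rescale: linearity makes this exact
  q_raw <- sum(sol) * h^2                       # flow rate of the raw solution
  if (!is.null(spec$mean_velocity)) {
    s <- spec$mean_velocity * area / q_raw
  } else {
    s <- spec$flow_rate / q_raw
  }
  u <- u * s
  G <- mu * s  # -lap u = G/mu with raw rhs 1

  flow_rate <- q_raw * s
  mean_velocity <- flow_rate / area

  bnd <- wall_shear_boundary(poly, pts, u, dwall, idx, nx, ny, h, mu)

  # arc-length weighted stats over valid samples (segments >= one grid cell)
  ok <- is.finite(bnd$tau)
  w <- bnd$ds[ok]
  structure(list(
    grid = list(x = xg, y = yg),
    u = matrix(u, nrow = nx, ncol = ny),
    boundary = bnd[, c("arc_length", "x", "y", "tau")],
    tau_mean = sum(bnd$tau[ok] * w) / sum(w),
    tau_max = max(bnd$tau[ok]),
    tau_min = min(bnd$tau[ok]),
    mean_velocity = mean_velocity,
    flow_rate = flow_rate,
    pressure_gradient = G,
    h = h
  ), class = "flow_solution")
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("Axial flow solution on %d x %d grid (h = %.3g um)\n",
              length(x$grid$x), length(x$grid$y), x$h))
  cat(sprintf("  mean velocity %.3g um/s, flow rate %.3g um^3/s\n",
              x$mean_velocity, x$flow_rate))
  cat(sprintf("  wall shear: mean %.3g, max %.3g, min %.3g Pa\n",
              x$tau_mean, x$tau_max, x$tau_min))
  invisible(x)
}

# crossing-number point-in-polygon, vectorized over points
points_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# exact Euclidean distance from points to the polygon boundary
dist_to_polygon <- function(pts, poly) {
  n <- nrow(poly)
  a <- poly
  b <- poly[c(2:n, 1), , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    apx <- pts[, 1] - a[i, 1]; apy <- pts[, 2] - a[i, 2]
    t <- pmin(1, pmax(0, (apx * ab[i, 1] + apy * ab[i, 2]) / len2[i]))
    dx <- apx - t * ab[i, 1]; dy <- apy - t * ab[i, 2]
    d2 <- pmin(d2, dx * dx + dy * dy)
  }
  sqrt(d2)
}

# Shortley-Weller solve of -lap u = 1, u = 0 on the polygon boundary
sw_poisson_solve <- function(pts, inside, nx, ny, h, poly) {
  idx <- which(inside)
  rank <- integer(nx * ny)
  rank[idx] <- seq_along(idx)
  m <- length(idx)

  off <- c(-1L, 1L, -nx, nx)                      # W, E, S, N in linear index
  dvec <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))

  # guard against wrap-around at grid edges
  col_i <- ((idx - 1L) %% nx) + 1L
  ti <- tj <- tv <- list()
  diag_v <- rep(0, m)
  k <- 1L
  for (d in 1:4) {
    nb <- idx + off[d]
    valid <- rep(TRUE, m)
    if (d == 1) valid <- col_i > 1L
    if (d == 2) valid <- col_i < nx
    nb_in <- valid & nb >= 1L & nb <= nx * ny & inside[pmin(pmax(nb, 1L), nx * ny)]
    hd <- rep(h, m)
    # boundary-cut neighbours: distance from node to wall along direction d
    cut <- which(!nb_in)
    if (length(cut)) {
      hd[cut] <- ray_boundary_distance(pts[idx[cut], , drop = FALSE],
                                       dvec[d, ], h, poly)
    }
    # assemble asymmetric SW stencil later; store per-direction spacing
    assign(paste0("h", d), hd)
  }
  hW <- get("h1"); hE <- get("h2"); hS <- get("h3"); hN <- get("h4")

  # u_xx ~ 2/(hE+hW) [ (uE-u)/hE - (u-uW)/hW ]; -lap u = 1
  cW <- 2 / (hW * (hE + hW)); cE <- 2 / (hE * (hE + hW))
  cS <- 2 / (hS * (hN + hS)); cN <- 2 / (hN * (hN + hS))
  diag_v <- cW + cE + cS + cN

  tripl_i <- seq_len(m); tripl_j <- seq_len(m); tripl_v <- diag_v
  hs <- cbind(cW, cE, cS, cN)
  for (d in 1:4) {
    nb <- idx + off[d]
    keep <- nb >= 1L & nb <= nx * ny
    if (d == 1) keep <- keep & col_i > 1L
    if (d == 2) keep <- keep & col_i < nx
    keep[keep] <- inside[nb[keep]]
    w <- which(keep)
    tripl_i <- c(tripl_i, w)
    tripl_j <- c(tripl_j, rank[nb[w]])
    tripl_v <- c(tripl_v, -hs[w, d])
  }
  A <- Matrix::sparseMatrix(i = tripl_i, j = tripl_j, x = tripl_v,
                            dims = c(m, m))
  # SW stencils are mildly asymmetric near the boundary; use a general solver
  as.numeric(Matrix::solve(A, rep(1, m)))
}

# distance (<= h) from each point to the polygon boundary along direction dvec
ray_boundary_distance <- function(p, dvec, h, poly) {
  n <- nrow(poly)
  a <- poly; b <- poly[c(2:n, 1), , drop = FALSE]
  tmin <- rep(h, nrow(p))  # fall back to h if no hit found (corner cases)
  for (i in seq_len(n)) {
    # solve p + t*dvec = a_i + s*(b_i - a_i)
    ex <- b[i, 1] - a[i, 1]; ey <- b[i, 2] - a[i, 2]
    den <- dvec[1] * (-ey) - dvec[2] * (-ex)
    if (abs(den) < 1e-300) next
    rx <- a[i, 1] - p[, 1]; ry <- a[i, 2] - p[, 2]
    t <- (rx * (-ey) + ex * ry) / den
    s <- (dvec[1] * ry - dvec[2] * rx) / den
    hit <- t > 1e-12 & t <= h * (1 + 1e-9) & s >= -1e-9 & s <= 1 + 1e-9
    tmin[hit] <- pmin(tmin[hit], t[hit])
  }
  pmax(tmin, 1e-3 * h)  # avoid singular stencils for grazing nodes
}

# wall shear by quadratic-in-distance LS fit of near-wall interior samples
wall_shear_boundary <- function(poly, pts, u, dwall, idx, nx, ny, h, mu) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  edge <- poly[nxt, , drop = FALSE] - poly
  elen <- sqrt(rowSums(edge^2))

  # resample boundary at ~h spacing
  nsub <- pmax(1L, ceiling(elen / h))
  samp_x <- samp_y <- samp_nx <- samp_ny <- samp_ds <- numeric(0)
  for (i in seq_len(n)) {
    tt <- (seq_len(nsub[i]) - 0.5) / nsub[i]
    samp_x <- c(samp_x, poly[i, 1] + tt * edge[i, 1])
    samp_y <- c(samp_y, poly[i, 2] + tt * edge[i, 2])
    # inward normal of a CCW polygon edge (t rotated +90 deg)
    tx <- edge[i, 1] / elen[i]; ty <- edge[i, 2] / elen[i]
    samp_nx <- c(samp_nx, rep(-ty, nsub[i]))
    samp_ny <- c(samp_ny, rep(tx, nsub[i]))
    samp_ds <- c(samp_ds, rep(elen[i] / nsub[i], nsub[i]))
  }
  ns <- length(samp_x)

  # spatial hash of near-wall interior nodes
  near <- idx[dwall[idx] <= 3.2 * h]
  px <- pts[near, 1]; py <- pts[near, 2]
  pu <- u[near]; pd <- dwall[near]

  x0 <- min(px); y0 <- min(py)
  cell <- 2.6 * h
  key <- function(x, y) paste(floor((x - x0) / cell), floor((y - y0) / cell))
  buckets <- split(seq_along(px), key(px, py))

  tau <- rep(NA_real_, ns)
  for (s in seq_len(ns)) {
    qx <- samp_x[s] + 1.2 * h * samp_nx[s]
    qy <- samp_y[s] + 1.2 * h * samp_ny[s]
    ci <- floor((qx - x0) / cell); cj <- floor((qy - y0) / cell)
    cand <- unlist(buckets[paste(rep(ci + (-1:1), each = 3), cj + (-1:1))],
                   use.names = FALSE)
    if (length(cand) < 4) next
    dx <- px[cand] - qx; dy <- py[cand] - qy
    sel <- cand[dx * dx + dy * dy <= (2.4 * h)^2]
    if (length(sel) < 4) next
    dd <- pd[sel]
    X <- cbind(dd, dd * dd)
    fit <- tryCatch(qr.coef(qr(X), pu[sel]), error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit[1])) next
    tau[s] <- mu * fit[1]
  }
  # fill isolated gaps from neighbours along the boundary loop
  if (anyNA(tau) && any(is.finite(tau))) {
    bad <- which(!is.finite(tau))
    good <- which(is.finite(tau))
    for (s in bad) {
      j <- good[which.min(pmin(abs(good - s), ns - abs(good - s)))]
      tau[s] <- tau[j]
    }
  }
  data.frame(arc_length = cumsum(samp_ds) - samp_ds / 2,
             x = samp_x, y = samp_y, tau = tau, ds = samp_ds)
}
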