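# --- mesh topology operations: T1 swaps, T2 removals, cell division -------

# indices of cells whose loop contains the (undirected) edge a-b
cells_with_edge <- function(mesh, a, b) {
  which(vapply(mesh$cells, function(cl) {
    n <- length(cl)
    nxt <- cl[c(2:n, 1)]
    any((cl == a & nxt == b) | (cl == b & nxt == a))
  }, logical(1)))
}

# add a vertex at 'pos' on edge a-b of every incident cell; returns mesh + id
insert_vertex_on_edge <- function(mesh, a, b, pos) {
  vid <- nrow(mesh$vertices) + 1L
  mesh$vertices <- rbind(mesh$vertices, pos)
  for (k in cells_with_edge(mesh, a, b)) {
    cl <- mesh$cells[[k]]
    n <- length(cl)
    nxt <- cl[c(2:n, 1)]
    i <- which((cl == a & nxt == b) | (cl == b & nxt == a))[1]
    mesh$cells[[k]] <- append(cl, vid, after = i)
  }
  list(mesh = mesh, vid = vid)
}

# T1 neighbour exchange on interior edge a-b; post-swap edge length new_len.
# Returns the updated mesh, or NULL when the swap is not applicable
# (boundary edge, triangular incident cell, ambiguous geometry).
t1_swap <- function(mesh, a, b, new_len) {
  inc <- cells_with_edge(mesh, a, b)
  if (length(inc) != 2) return(NULL)
  P <- inc[1]; Q <- inc[2]
  if (length(mesh$cells[[P]]) <= 3 || length(mesh$cells[[Q]]) <= 3) return(NULL)
  has_a <- which(vapply(mesh$cells, function(cl) a %in% cl, logical(1)))
  has_b <- which(vapply(mesh$cells, function(cl) b %in% cl, logical(1)))
  R <- setdiff(has_a, inc)   # cell touching a only (may be empty at boundary)
  S <- setdiff(has_b, inc)
  if (length(R) > 1 || length(S) > 1) return(NULL)

  va <- mesh$vertices[a, ]; vb <- mesh$vertices[b, ]
  m <- (va + vb) / 2
  d <- vb - va
  dl <- sqrt(sum(d^2))
  if (dl < 1e-14) {
    perp <- c(0, 1)
  } else {
    perp <- c(-d[2], d[1]) / dl
  }
  new_a <- m + perp * new_len / 2
  new_b <- m - perp * new_len / 2

  old_v <- mesh$vertices
  mesh$vertices[a, ] <- new_a
  mesh$vertices[b, ] <- new_b

  # P and Q each keep the rotated endpoint nearest their centroid
  keep <- integer(2)
  for (i in 1:2) {
    k <- inc[i]
    ctr <- polygon_centroid(old_v[mesh$cells[[k]], , drop = FALSE])
    keep[i] <- if (sum((ctr - new_a)^2) < sum((ctr - new_b)^2)) a else b
  }
  if (keep[1] == keep[2]) { mesh$vertices <- old_v; return(NULL) }
  for (i in 1:2) {
    drop_v <- if (keep[i] == a) b else a
    mesh$cells[[inc[i]]] <- setdiff(mesh$cells[[inc[i]]], drop_v)
  }
  # R gains b next to a; S gains a next to b — choose the insertion side
  # that leaves a simple, positively oriented polygon
  gain <- function(k, have, add) {
    cl <- mesh$cells[[k]]
    i <- which(cl == have)
    cand <- list(append(cl, add, after = i),
                 append(cl, add, after = i - 1L))
    for (cc in cand) {
      xy <- mesh$vertices[cc, , drop = FALSE]
      if (polygon_area(xy) > 0 && is_simple_polygon(xy)) return(cc)
    }
    NULL
  }
  if (length(R) == 1) {
    cc <- gain(R, a, b)
    if (is.null(cc)) { mesh$vertices <- old_v; return(NULL) }
    mesh$cells[[R]] <- cc
  }
  if (length(S) == 1) {
    cc <- gain(S, b, a)
    if (is.null(cc)) { mesh$vertices <- old_v; return(NULL) }
    mesh$cells[[S]] <- cc
  }
  mesh
}

# T2: remove a collapsed (triangular) cell, merging its vertices into one
t2_remove <- function(mesh, cell_id) {
  cl <- mesh$cells[[cell_id]]
  if (length(cl) != 3) return(NULL)
  ctr <- colMeans(mesh$vertices[cl, , drop = FALSE])
  vid <- nrow(mesh$vertices) + 1L
  mesh$vertices <- rbind(mesh$vertices, ctr)
  mesh$cells[[cell_id]] <- NULL
  mesh$cells <- lapply(mesh$cells, function(cc) {
    cc[cc %in% cl] <- vid
    cc[c(TRUE, cc[-1] != cc[-length(cc)])]  # drop consecutive duplicates
  })
  # drop a duplicate across the loop seam
  mesh$cells <- lapply(mesh$cells, function(cc) {
    if (length(cc) > 1 && cc[1] == cc[length(cc)]) cc <- cc[-length(cc)]
    cc
  })
  # neighbours reduced to < 3 vertices by the merge are dropped as well
  keep <- lengths(mesh$cells) >= 3
  mesh$cells <- mesh$cells[keep]
  # map back to the caller's pre-removal cell ids (cell_id already deleted)
  old_ids <- setdiff(seq_len(length(keep) + 1L), cell_id)
  list(mesh = mesh, kept_cells = old_ids[keep])
}

# second-moment (covariance) tensor of a polygon about its centroid
polygon_covariance <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  A <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * A)
  cy <- sum((y + yn) * cr) / (6 * A)
  exx <- sum((x^2 + x * xn + xn^2) * cr) / (12 * A)
  eyy <- sum((y^2 + y * yn + yn^2) * cr) / (12 * A)
  exy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / (24 * A)
  matrix(c(exx - cx^2, exy - cx * cy, exy - cx * cy, eyy - cy^2), 2, 2)
}

# intersection of the line ctr + t*dir with the polygon boundary; returns the
# two crossings nearest the centroid on either side, or NULL
split_points <- function(xy, ctr, dir) {
  n <- nrow(xy)
  a <- xy; b <- xy[c(2:n, 1), , drop = FALSE]
  hits <- NULL
  for (i in seq_len(n)) {
    e <- b[i, ] - a[i, ]
    den <- dir[1] * e[2] - dir[2] * e[1]
    if (abs(den) < 1e-14) next
    r <- a[i, ] - ctr
    t <- (r[1] * e[2] - r[2] * e[1]) / den
    ss <- (dir[1] * r[2] - dir[2] * r[1]) / (-den)
    if (ss > 1e-9 && ss < 1 - 1e-9) {
      hits <- rbind(hits, c(t = t, edge = i, s = ss))
    }
  }
  if (is.null(hits) || !any(hits[, 1] > 0) || !any(hits[, 1] < 0)) return(NULL)
  pos <- hits[hits[, 1] > 0, , drop = FALSE]
  neg <- hits[hits[, 1] < 0, , drop = FALSE]
  list(p1 = pos[which.min(pos[, 1]), ], p2 = neg[which.max(neg[, 1]), ])
}

#' Divide a cell along its shortest centroid axis
#'
#' Splits a proliferative cell by the line through its area centroid along
#' the shortest principal axis of its polygon (the second-moment tensor),
#' i.e. perpendicular to the longest axis — Hertwig's rule. Daughters
#' inherit the mother's base target area, get age 0 and freshly sampled
#' cycle duration and division-area threshold. For degenerate principal
#' axes (eigenvalue ratio within 1e-6, e.g. a regular hexagon) the division
#' axis is drawn uniformly at random. If a split line fails to produce two
#' simple polygons it is retried with a ±5° jitter before erroring.
#'
#' @param mesh A [tissue_mesh()].
#' @param states Cell-state data frame.
#' @param cell_id Cell to divide (must be proliferative).
#' @param params A [vertex_params()] (Gaussian resampling parameters and the
#'   optional aspect-ratio threshold for random-axis division).
#' @param time Simulation time recorded in the division record.
#' @return List with `mesh`, `states`, and `record` (data frame row: time,
#'   mother, daughter1, daughter2, division_angle in degrees folded into 0..90
#'   relative to the longitudinal y axis).
#' @export
divide_cell <- function(mesh, states, cell_id, params = vertex_params(),
                        time = NA_real_) {
  if (!states$proliferative[cell_id]) stop("cell ", cell_id, " is differentiated")
  cl <- mesh$cells[[cell_id]]
  xy <- mesh$vertices[cl, , drop = FALSE]
  ctr <- polygon_centroid(xy)
  cov <- polygon_covariance(xy)
  eg <- eigen(cov, symmetric = TRUE)
  # shortest axis = eigenvector of the smaller eigenvalue
  degenerate <- (eg$values[1] - eg$values[2]) <= 1e-6 * eg$values[1]
  aspect <- sqrt(eg$values[1] / max(eg$values[2], 1e-300))
  random_axis <- degenerate ||
    (!is.null(params$hertwig_aspect_threshold) &&
       aspect < params$hertwig_aspect_threshold)
  if (random_axis) {
    th <- stats::runif(1, 0, pi)
    dir <- c(cos(th), sin(th))
  } else {
    dir <- eg$vectors[, 2]
  }

  attempt <- function(dir) {
    sp <- split_points(xy, ctr, dir)
    if (is.null(sp)) return(NULL)
    p1 <- ctr + sp$p1["t"] * dir
    p2 <- ctr + sp$p2["t"] * dir
    e1 <- sp$p1["edge"]; e2 <- sp$p2["edge"]
    n <- length(cl)
    a1 <- cl[e1]; b1 <- cl[if (e1 == n) 1 else e1 + 1]
    a2 <- cl[e2]; b2 <- cl[if (e2 == n) 1 else e2 + 1]
    m2 <- insert_vertex_on_edge(mesh, a1, b1, p1)
    v1 <- m2$vid
    m2 <- insert_vertex_on_edge(m2$mesh, a2, b2, p2)
    v2 <- m2$vid
    mm <- m2$mesh
    loop <- mm$cells[[cell_id]]
    i1 <- which(loop == v1); i2 <- which(loop == v2)
    if (!length(i1) || !length(i2)) return(NULL)
    roll <- function(l, from, to) {
      if (from <= to) l[from:to] else c(l[from:length(l)], l[1:to])
    }
    d1 <- roll(loop, i1, i2)
    d2 <- roll(loop, i2, i1)
    if (length(d1) < 3 || length(d2) < 3) return(NULL)
    xy1 <- mm$vertices[d1, , drop = FALSE]
    xy2 <- mm$vertices[d2, , drop = FALSE]
    if (polygon_area(xy1) <= 0 || polygon_area(xy2) <= 0) return(NULL)
    if (!is_simple_polygon(xy1) || !is_simple_polygon(xy2)) return(NULL)
    list(mesh = mm, d1 = d1, d2 = d2)
  }

  res <- attempt(dir)
  if (is.null(res)) {
    for (jit in c(5, -5) * pi / 180) {
      rot <- matrix(c(cos(jit), sin(jit), -sin(jit), cos(jit)), 2, 2)
      res <- attempt(as.numeric(rot %*% dir))
      if (!is.null(res)) break
    }
  }
  if (is.null(res)) {
    stop("division of cell ", cell_id, " failed to produce two simple polygons")
  }

  mesh <- res$mesh
  mesh$cells[[cell_id]] <- res$d1
  mesh$cells[[length(mesh$cells) + 1L]] <- res$d2
  id2 <- length(mesh$cells)

  # daughter states: resampled stochastic parameters, inherited base target
  resample <- function() {
    c(truncated_normal(1, params$cycle_mean, params$cycle_sd,
                       lower = 0.05 * params$cycle_mean),
      truncated_normal(1, params$div_area_mean, params$div_area_sd,
                       lower = 0.2))
  }
  s1 <- resample(); s2 <- resample()
  states$age[cell_id] <- 0
  states$cycle_duration[cell_id] <- s1[1]
  states$division_area_threshold[cell_id] <- s1[2]
  new_row <- states[cell_id, , drop = FALSE]  # inherit any extra columns
  new_row$cell <- id2
  new_row$cycle_duration <- s2[1]
  new_row$division_area_threshold <- s2[2]
  states <- rbind(states, new_row)
  states$cell <- seq_len(nrow(states))
  rownames(states) <- NULL

  c1 <- polygon_centroid(mesh$vertices[res$d1, , drop = FALSE])
  c2 <- polygon_centroid(mesh$vertices[res$d2, , drop = FALSE])
  axis <- c2 - c1
  ang <- acos(min(1, abs(axis[2]) / sqrt(sum(axis^2)))) * 180 / pi
  record <- data.frame(time = time, mother = cell_id, daughter1 = cell_id,
                       daughter2 = id2, division_angle = ang)
  list(mesh = mesh, states = states, record = record)
}
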