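#' Honeycomb tissue with sampled cell states
#'
#' Builds the initial vertex-model configuration: `n_cells` unit-area
#' hexagons in offset rows ("pointy-top", so the tissue's longitudinal axis
#' is y), trimmed to approximate the requested bounding-box aspect ratio.
#' Cells in the top-most and bottom-most rows are flagged differentiated:
#' they never divide and carry the external boundary forces. Cycle durations
#' and division-area thresholds are drawn per cell from the configured
#' Gaussians; initial ages are uniform on `[0, cycle)` so divisions are
#' desynchronized from the start.
#'
#' @param n_cells Number of cells (>= 9).
#' @param aspect_ratio Target height/width of the tissue bounding box.
#' @param seed RNG seed (mandatory: states are sampled).
#' @param params A [vertex_params()] supplying the Gaussian parameters.
#' @return List with `mesh` (a [tissue_mesh()]) and `states` (data frame:
#'   `cell`, `target_area`, `age`, `cycle_duration`,
#'   `division_area_threshold`, `proliferative`).
#' @examples
#' hc <- make_honeycomb(16, seed = 1)
#' hc$mesh
#' @export
make_honeycomb <- function(n_cells = 100, aspect_ratio = 1, seed,
                           params = vertex_params()) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(n_cells >= 9, aspect_ratio > 0)
  s <- sqrt(2 / (3 * sqrt(3)))  # circumradius of a unit-area hexagon
  w <- sqrt(3) * s              # horizontal pitch

  # choose a column count whose filled layout best matches the aspect;
  # the last (top) row may be partial but must hold at least 2 cells so the
  # differentiated top row is meaningful
  best <- NULL
  for (ncol_ in 2:max(3L, ceiling(sqrt(n_cells)) * 2L)) {
    full <- n_cells %/% ncol_
    rem <- n_cells - full * ncol_
    nrow_used <- full + (rem > 0L)
    if (nrow_used < 3) next
    if (rem == 1L) next
    height <- 1.5 * s * (nrow_used - 1) + 2 * s
    width <- w * (ncol_ + 0.5)
    sc <- abs(log((height / width) / aspect_ratio))
    if (is.null(best) || sc < best$score) {
      best <- list(nrow = nrow_used, ncol = ncol_, score = sc)
    }
  }
  if (is.null(best)) stop("impossible n_cells / aspect_ratio combination")
  nr <- best$nrow; ncl <- best$ncol

  # hexagon centres, filling rows bottom-up; last row may be partial
  centres <- NULL
  rows <- integer(0)
  count <- 0L
  for (r in seq_len(nr)) {
    take <- min(ncl, n_cells - count)
    if (take <= 0) break
    cx <- w * (seq_len(take) + 0.5 * ((r - 1) %% 2))
    cy <- 1.5 * s * (r - 1)
    centres <- rbind(centres, cbind(cx, rep(cy, take)))
    rows <- c(rows, rep(r, take))
    count <- count + take
  }
  n_rows_used <- max(rows)

  # hexagon vertices (shared via coordinate hashing)
  ang <- pi / 6 + (0:5) * pi / 3  # pointy-top
  vx <- as.vector(outer(s * cos(ang), centres[, 1], `+`))
  vy <- as.vector(outer(s * sin(ang), centres[, 2], `+`))
  key <- paste(round(vx / (1e-6 * s)), round(vy / (1e-6 * s)))
  uid <- match(key, unique(key))
  first <- !duplicated(key)
  vertices <- cbind(vx[first], vy[first])
  cells <- unname(split(uid, rep(seq_len(nrow(centres)), each = 6)))

  # area-preserving anisotropic rescale to hit the requested bounding-box
  # aspect exactly (integer row/column layouts only approximate it)
  bb <- apply(vertices, 2, range)
  asp_actual <- (bb[2, 2] - bb[1, 2]) / (bb[2, 1] - bb[1, 1])
  k <- sqrt(aspect_ratio / asp_actual)
  if (!is.finite(k) || k < 0.7 || k > 1.4) {
    stop("impossible n_cells / aspect_ratio combination")
  }
  vertices[, 1] <- vertices[, 1] / k
  vertices[, 2] <- vertices[, 2] * k

  mesh <- tissue_mesh(vertices, cells)

  proliferative <- !(rows == 1L | rows == n_rows_used)
  set.seed(seed)
  cyc <- truncated_normal(n_cells, params$cycle_mean, params$cycle_sd,
                          lower = 0.05 * params$cycle_mean)
  thr <- truncated_normal(n_cells, params$div_area_mean, params$div_area_sd,
                          lower = 0.2)
  states <- data.frame(
    cell = seq_len(n_cells),
    target_area = 1,
    age = stats::runif(n_cells, 0, cyc),
    cycle_duration = cyc,
    division_area_threshold = thr,
    proliferative = proliferative
  )
  list(mesh = mesh, states = states)
}

truncated_normal <- function(n, mean, sd, lower) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lower)
  guard <- 0L
  while (length(bad) && guard < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
    guard <- guard + 1L
  }
  x[x <= lower] <- lower
  x
}
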