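#' Vertex-model parameters
#'
#' All mechanical and stochastic parameters of the apical vertex model, in
#' model units (a.u.). The energy of a tissue configuration is
#' \deqn{U = \sum_k \lambda (A_k - A_{0,k})^2 + \sum_k \beta (C_k - C_{0,k})^2
#'       + \sum_{edges} \gamma \, \ell,}
#' with per-cell area \eqn{A_k}, perimeter \eqn{C_k}, and an edge-class
#' dependent line tension (cell-cell contacts vs the free tissue boundary).
#' Cell targets grow linearly over the cycle: a cell of age \eqn{\tau} and
#' cycle duration \eqn{T} has \eqn{A_{0,k} = A_0 (1 + \tau/T)}, reaching
#' twice the base target at its nominal division time; the target perimeter
#' tracks the target area as \eqn{C_{0,k} = c_0 \sqrt{A_{0,k}}}.
#'
#' `boundary_force` is the longitudinal elongation force per boundary-layer
#' vertex, in the anchored force unit: the raw model force is
#' `boundary_force * force_unit`. The default `force_unit` is calibrated so
#' that a force of 1.0 a.u. reproduces the 2-fold elongation bias observed
#' for embryonic lung tubes (see the package vignette).
#'
#' Gaussian cycle durations and division-area thresholds (`cycle_*`,
#' `div_area_*`) are calibrated so the unforced simulation reproduces an
#' apical area coefficient of variation of 0.6 and a hexagon fraction of
#' 30%.
#'
#' @param lambda_area Area-elasticity coefficient.
#' @param beta_perimeter Perimeter-elasticity coefficient.
#' @param gamma_cc Line tension of cell-cell edges.
#' @param gamma_boundary Line tension of free boundary edges.
#' @param target_shape Target shape index \eqn{c_0 = C_0/\sqrt{A_0}}.
#' @param drag Vertex drag coefficient (inverse mobility).
#' @param dt Base integration time step.
#' @param t1_threshold Edge length triggering a T1 swap; `NULL` means 1% of
#'   the initial mean edge length.
#' @param boundary_force Elongation force per boundary-layer vertex (a.u.).
#' @param force_unit Raw model force corresponding to 1 a.u. of
#'   `boundary_force`.
#' @param cycle_mean,cycle_sd Gaussian cell-cycle duration parameters (a.u.).
#' @param div_area_mean,div_area_sd Gaussian division-area threshold
#'   parameters (a.u.^2).
#' @param duration Total simulated time (a.u.).
#' @param t1_enabled,t2_enabled Enable neighbour exchanges / removal of
#'   collapsed triangular cells.
#' @param hertwig_aspect_threshold If non-`NULL`, cells with principal-axis
#'   aspect ratio below this value divide along a uniformly random axis
#'   instead of the shortest axis (biological threshold 1.53); default off:
#'   always the shortest axis.
#' @param seed RNG seed.
#' @return An object of class `vertex_params` (a list).
#' @export
vertex_params <- function(lambda_area = 100, beta_perimeter = 10,
                          gamma_cc = 1, gamma_boundary = 10,
                          target_shape = 3.55,
                          drag = 1, dt = 0.002, t1_threshold = NULL,
                          boundary_force = 0, force_unit = 1.5,
                          cycle_mean = 10, cycle_sd = 5,
                          div_area_mean = 4, div_area_sd = 3,
                          duration = 48, t1_enabled = TRUE, t2_enabled = TRUE,
                          hertwig_aspect_threshold = NULL, seed = 1L) {
  p <- list(lambda_area = lambda_area, beta_perimeter = beta_perimeter,
            gamma_cc = gamma_cc, gamma_boundary = gamma_boundary,
            target_shape = target_shape, drag = drag, dt = dt,
            t1_threshold = t1_threshold, boundary_force = boundary_force,
            force_unit = force_unit, cycle_mean = cycle_mean,
            cycle_sd = cycle_sd, div_area_mean = div_area_mean,
            div_area_sd = div_area_sd, duration = duration,
            t1_enabled = t1_enabled, t2_enabled = t2_enabled,
            hertwig_aspect_threshold = hertwig_aspect_threshold,
            seed = as.integer(seed))
  num <- c("lambda_area", "beta_perimeter", "gamma_cc", "gamma_boundary",
           "drag", "dt", "cycle_mean", "cycle_sd", "div_area_mean",
           "div_area_sd", "duration")
  for (f in num) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0) stop("'", f, "' must be >= 0")
  }
  if (p$dt <= 0 || p$drag <= 0) stop("dt and drag must be > 0")
  structure(p, class = "vertex_params")
}

# effective (growing) targets for the current cell states
effective_targets <- function(states, params) {
  grow <- ifelse(states$proliferative,
                 1 + states$age / states$cycle_duration, 1)
  A0 <- states$target_area * grow
  list(A0 = A0, C0 = params$target_shape * sqrt(A0))
}

#' Potential energy of a tissue configuration
#'
#' Evaluates the three-term vertex-model energy: area elasticity, perimeter
#' (contractility) elasticity, and line tension, with each edge counted
#' once (cell-cell tension `gamma_cc`, boundary tension `gamma_boundary`).
#'
#' @param mesh A [tissue_mesh()].
#' @param states Cell-state data frame as produced by [make_honeycomb()].
#' @param params A [vertex_params()].
#' @return List with `total`, `area`, `perimeter`, `line` (a.u.).
#' @export
potential_energy <- function(mesh, states, params = vertex_params()) {
  A <- cell_areas(mesh)
  if (any(abs(A) < 1e-12)) {
    stop("degenerate (zero-area) cell: ",
         paste(which(abs(A) < 1e-12), collapse = ", "))
  }
  C <- cell_perimeters(mesh)
  tg <- effective_targets(states, params)
  U_A <- params$lambda_area * sum((A - tg$A0)^2)
  U_C <- params$beta_perimeter * sum((C - tg$C0)^2)

  sl <- mesh_slots(mesh)
  d <- mesh$vertices[sl$svnext, , drop = FALSE] -
    mesh$vertices[sl$sv, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  gam <- ifelse(sl$edge_mult == 2L, params$gamma_cc / 2, params$gamma_boundary)
  U_L <- sum(gam * len)
  list(total = U_A + U_C + U_L, area = U_A, perimeter = U_C, line = U_L)
}

#' Vertex forces of a tissue configuration
#'
#' Returns the negative energy gradient per vertex plus the external
#' longitudinal boundary forces: every vertex of a differentiated top-row
#' cell receives `+f` along y, every vertex of a differentiated bottom-row
#' cell `-f`, with `f = boundary_force * force_unit`.
#'
#' @inheritParams potential_energy
#' @param engine `"r"` (reference implementation) or `"cpp"` (fast engine;
#'   identical results, used by [run_simulation()]).
#' @return n_vertices x 2 matrix of forces.
#' @export
vm_forces <- function(mesh, states, params = vertex_params(), engine = "r") {
  tg <- effective_targets(states, params)
  sl <- mesh_slots(mesh)
  gam <- ifelse(sl$edge_mult == 2L, params$gamma_cc / 2, params$gamma_boundary)
  fext <- external_forces(mesh, states, params)
  if (engine == "cpp") {
    A <- cell_areas(mesh)  # only for the degenerate-cell guard
    if (any(abs(A) < 1e-12)) stop("degenerate (zero-area) cell")
    F <- vm_forces_cpp(mesh$vertices, sl$sv - 1L, sl$svnext - 1L,
                       sl$svprev - 1L, sl$scell - 1L, length(mesh$cells),
                       tg$A0, tg$C0, gam, params$lambda_area,
                       params$beta_perimeter)
    F <- F + fext
  } else {
    F <- vm_forces_r(mesh, tg, gam, params) + fext
  }
  if (any(!is.finite(F))) stop("non-finite force encountered")
  F
}

vm_forces_r <- function(mesh, tg, gam, params) {
  V <- mesh$vertices
  sl <- mesh_slots(mesh)
  A <- cell_areas(mesh)
  if (any(abs(A) < 1e-12)) {
    stop("degenerate (zero-area) cell: ",
         paste(which(abs(A) < 1e-12), collapse = ", "))
  }
  C <- cell_perimeters(mesh)
  cA <- 2 * params$lambda_area * (A - tg$A0)   # dU/dA per cell
  cC <- 2 * params$beta_perimeter * (C - tg$C0)

  xs <- V[sl$sv, 1]; ys <- V[sl$sv, 2]
  xn <- V[sl$svnext, 1]; yn <- V[sl$svnext, 2]
  xp <- V[sl$svprev, 1]; yp <- V[sl$svprev, 2]

  # area gradient: dA/dv_i = 0.5 * (y_next - y_prev, x_prev - x_next)
  gAx <- 0.5 * (yn - yp); gAy <- 0.5 * (xp - xn)
  fx <- -cA[sl$scell] * gAx
  fy <- -cA[sl$scell] * gAy

  # perimeter gradient: unit vectors to both neighbours
  ln <- sqrt((xs - xn)^2 + (ys - yn)^2)
  lp <- sqrt((xs - xp)^2 + (ys - yp)^2)
  ln[ln < 1e-14] <- 1e-14; lp[lp < 1e-14] <- 1e-14
  gCx <- (xs - xn) / ln + (xs - xp) / lp
  gCy <- (ys - yn) / ln + (ys - yp) / lp
  fx <- fx - cC[sl$scell] * gCx
  fy <- fy - cC[sl$scell] * gCy

  # line tension on the slot edge (v -> next); acts on both endpoints
  fx <- fx - gam * (xs - xn) / ln
  fy <- fy - gam * (ys - yn) / ln
  fnx <- -gam * (xn - xs) / ln
  fny <- -gam * (yn - ys) / ln

  Fx <- rowsum(c(fx, fnx), c(sl$sv, sl$svnext))
  Fy <- rowsum(c(fy, fny), c(sl$sv, sl$svnext))
  out <- matrix(0, nrow(V), 2)
  out[as.integer(rownames(Fx)), 1] <- Fx
  out[as.integer(rownames(Fy)), 2] <- Fy
  out
}

# external longitudinal forces on differentiated boundary-layer vertices
external_forces <- function(mesh, states, params) {
  F <- matrix(0, nrow(mesh$vertices), 2)
  f <- params$boundary_force * params$force_unit
  if (f == 0 || !any(!states$proliferative)) return(F)
  diff_cells <- which(!states$proliferative)
  ctr <- cell_centroids(mesh)
  mid <- mean(ctr[, 2])
  top <- diff_cells[ctr[diff_cells, 2] > mid]
  bot <- diff_cells[ctr[diff_cells, 2] <= mid]
  vtop <- unique(unlist(mesh$cells[top], use.names = FALSE))
  vbot <- unique(unlist(mesh$cells[bot], use.names = FALSE))
  F[vtop, 2] <- F[vtop, 2] + f
  F[vbot, 2] <- F[vbot, 2] - f
  F
}
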