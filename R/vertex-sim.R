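#' Single explicit vertex-model step (reference path)
#'
#' Moves every vertex by `dt * force / drag` (overdamped dynamics), applies
#' T1 neighbour exchanges to interior edges shorter than the threshold,
#' and increments cell ages. Asserts the time-step displacement bound
#' (max displacement below the T1 threshold). This is the readable
#' reference path; [run_simulation()] uses the compiled engine.
#'
#' @inheritParams potential_energy
#' @param dt Time step; defaults to `params$dt`.
#' @return List with updated `mesh` and `states`.
#' @export
vm_step <- function(mesh, states, params = vertex_params(), dt = params$dt) {
  F <- vm_forces(mesh, states, params)
  disp <- dt * F / params$drag
  t1_thr <- params$t1_threshold
  if (is.null(t1_thr)) t1_thr <- 0.01 * mean_edge_length(mesh)
  if (max(abs(disp)) >= t1_thr) {
    stop("time step too large: vertex displacement exceeds the T1 threshold")
  }
  mesh$vertices <- mesh$vertices + disp
  states$age <- states$age + dt
  if (params$t1_enabled) {
    ed <- mesh_edges(mesh)
    ed <- ed[ed$n_cells == 2L, , drop = FALSE]
    if (nrow(ed)) {
      len <- sqrt(rowSums((mesh$vertices[ed$a, , drop = FALSE] -
                             mesh$vertices[ed$b, , drop = FALSE])^2))
      for (i in which(len < t1_thr)) {
        m2 <- t1_swap(mesh, ed$a[i], ed$b[i], 1.5 * t1_thr)
        if (!is.null(m2)) mesh <- m2
      }
    }
  }
  list(mesh = mesh, states = states)
}

#' Run a proliferating vertex-model simulation
#'
#' Simulates a honeycomb tissue with differentiated (non-dividing) top and
#' bottom rows under longitudinally biased boundary forces: overdamped
#' vertex dynamics with an adaptive time step (per-step displacement capped
#' at a quarter of the T1 threshold, edge lengths checked every step), T1 neighbour exchanges, T2 removal of
#' collapsed triangles, and shortest-axis cell division triggered when a
#' cell's age exceeds its sampled cycle duration and its area exceeds its
#' sampled division threshold. Deterministic for a fixed seed.
#'
#' @param params A [vertex_params()].
#' @param n_cells,aspect_ratio Initial honeycomb layout (default 100 cells,
#'   aspect 1).
#' @param snapshot_every Snapshot cadence in simulation time (a.u.).
#' @param check_every Cadence of division/T2 checks (a.u.).
#' @param burn_in Force-free, division-free relaxation time before the
#'   initial snapshot. The generated honeycomb is mildly pre-strained by
#'   the aspect-ratio fit, so tissue extents are measured from the relaxed
#'   state; without this the early relaxation would masquerade as
#'   anisotropic growth.
#' @param progress Print progress lines.
#' @return An object of class `vm_trajectory`: list with `snapshots` (each
#'   `time` plus a per-cell table: id, origin, x, y, area, perimeter,
#'   n_neighbours, boundary, proliferative), `divisions` (a data frame of
#'   division records), `mesh_initial`, `mesh_final`, `states_final`,
#'   `params`, `stats` (final [shape_statistics()], outgrowth bias).
#' @export
run_simulation <- function(params = vertex_params(), n_cells = 100,
                           aspect_ratio = 1, snapshot_every = 4,
                           check_every = 0.2, burn_in = 2, progress = FALSE) {
  stopifnot(inherits(params, "vertex_params"))
  hc <- make_honeycomb(n_cells, aspect_ratio, seed = params$seed, params)
  mesh <- hc$mesh
  states <- hc$states
  states$origin <- states$cell
  mesh_initial <- mesh

  t1_thr <- params$t1_threshold
  if (is.null(t1_thr)) t1_thr <- 0.01 * mean_edge_length(mesh)
  disp_max <- 0.25 * t1_thr

  # burn-in: relax the generator's residual pre-strain before measuring
  if (burn_in > 0) {
    t_relax <- 0
    while (t_relax < burn_in) {
      sl <- mesh_slots(mesh)
      gam <- ifelse(sl$edge_mult == 2L, params$gamma_cc / 2,
                    params$gamma_boundary)
      tg <- effective_targets(states, params)
      ed <- mesh_edges(mesh)
      edi <- ed[ed$n_cells == 2L, , drop = FALSE]
      res <- vm_relax_cpp(mesh$vertices, sl$sv - 1L, sl$svnext - 1L,
                          sl$svprev - 1L, sl$scell - 1L, length(mesh$cells),
                          tg$A0, numeric(length(mesh$cells)),
                          params$target_shape, gam,
                          matrix(0, nrow(mesh$vertices), 2),
                          params$lambda_area, params$beta_perimeter,
                          params$drag, params$dt, disp_max,
                          burn_in - t_relax, edi$a - 1L, edi$b - 1L, t1_thr,
                          params$t1_enabled && nrow(edi) > 0, 500000L)
      mesh$vertices <- res$V
      t_relax <- t_relax + res$t
      if (res$status == 1) {
        m2 <- t1_swap(mesh, edi$a[res$short_edge], edi$b[res$short_edge],
                      1.5 * t1_thr)
        if (!is.null(m2)) mesh <- m2 else break
      }
      if (res$status == 3) stop("non-finite force during burn-in")
    }
  }

  snapshots <- list(snapshot_cells(mesh, states, 0))
  next_snap <- snapshot_every
  divisions <- list()
  t <- 0

  while (t < params$duration - 1e-9) {
    t_next <- min(t + check_every, params$duration)
    skip_edges <- character(0)
    repeat {
      sl <- mesh_slots(mesh)
      gam <- ifelse(sl$edge_mult == 2L, params$gamma_cc / 2,
                    params$gamma_boundary)
      tg <- effective_targets(states, params)
      dA0dt <- ifelse(states$proliferative,
                      states$target_area / states$cycle_duration, 0)
      fext <- external_forces(mesh, states, params)
      ed <- mesh_edges(mesh)
      edi <- ed[ed$n_cells == 2L, , drop = FALSE]
      if (length(skip_edges)) {
        edi <- edi[!(paste(edi$a, edi$b) %in% skip_edges), , drop = FALSE]
      }
      res <- vm_relax_cpp(mesh$vertices, sl$sv - 1L, sl$svnext - 1L,
                          sl$svprev - 1L, sl$scell - 1L, length(mesh$cells),
                          tg$A0, dA0dt, params$target_shape, gam, fext,
                          params$lambda_area, params$beta_perimeter,
                          params$drag, params$dt, disp_max, t_next - t,
                          edi$a - 1L, edi$b - 1L, t1_thr,
                          params$t1_enabled && nrow(edi) > 0, 500000L)
      mesh$vertices <- res$V
      states$age <- states$age + res$t
      t <- t + res$t
      if (res$status == 3) stop("non-finite force encountered at t = ", t)
      if (res$status == 1) {
        a <- edi$a[res$short_edge]; b <- edi$b[res$short_edge]
        m2 <- if (params$t1_enabled) t1_swap(mesh, a, b, 1.5 * t1_thr) else NULL
        if (is.null(m2)) {
          skip_edges <- c(skip_edges, paste(a, b))
        } else {
          mesh <- m2
        }
        next
      }
      if (res$status == 0) break
    }

    # T2: drop collapsed triangles
    if (params$t2_enabled) {
      repeat {
        A <- cell_areas(mesh)
        tiny <- which(lengths(mesh$cells) == 3L & A < 0.01 * mean(A))
        if (!length(tiny)) break
        t2 <- t2_remove(mesh, tiny[1])
        if (is.null(t2)) break
        mesh <- t2$mesh
        states <- states[t2$kept_cells, , drop = FALSE]
        states$cell <- seq_len(nrow(states))
      }
    }

    # divisions (one at a time; areas change after each split)
    repeat {
      A <- cell_areas(mesh)
      due <- which(states$proliferative &
                     states$age >= states$cycle_duration &
                     A >= states$division_area_threshold)
      if (!length(due)) break
      dv <- divide_cell(mesh, states, due[1], params, time = t)
      mesh <- dv$mesh
      states <- dv$states
      divisions[[length(divisions) + 1L]] <- dv$record
    }

    if (t >= next_snap - 1e-9 || t >= params$duration - 1e-9) {
      snapshots[[length(snapshots) + 1L]] <- snapshot_cells(mesh, states, t)
      next_snap <- next_snap + snapshot_every
      if (progress) {
        message(sprintf("t = %5.1f | %d cells | %d divisions",
                        t, length(mesh$cells), length(divisions)))
      }
    }
  }

  divisions <- if (length(divisions)) do.call(rbind, divisions) else
    data.frame(time = numeric(0), mother = integer(0), daughter1 = integer(0),
               daughter2 = integer(0), division_angle = numeric(0))
  traj <- structure(list(snapshots = snapshots, divisions = divisions,
                         mesh_initial = mesh_initial, mesh_final = mesh,
                         states_final = states, params = params),
                    class = "vm_trajectory")
  traj$stats <- c(shape_statistics(mesh),
                  list(elongation_bias = compute_outgrowth_bias(traj),
                       n_cells_final = length(mesh$cells),
                       n_divisions = nrow(divisions)))
  traj
}

snapshot_cells <- function(mesh, states, time) {
  ctr <- cell_centroids(mesh)
  nb <- mesh_neighbours(mesh)
  list(time = time,
       cells = data.frame(id = states$cell, origin = states$origin,
                          x = ctr[, 1], y = ctr[, 2],
                          area = cell_areas(mesh),
                          perimeter = cell_perimeters(mesh),
                          n_neighbours = nb$n_neighbours,
                          boundary = nb$boundary,
                          proliferative = states$proliferative))
}

#' @export
print.vm_trajectory <- function(x, ...) {
  s <- x$stats
  cat(sprintf("Vertex-model trajectory: %d snapshots, %d -> %d cells, %d divisions\n",
              length(x$snapshots), nrow(x$snapshots[[1]]$cells),
              s$n_cells_final, s$n_divisions))
  cat(sprintf("  elongation bias %.3f | area CV %.3f | hexagons %.1f%%\n",
              s$elongation_bias, s$area_cv,
              100 * s$polygon_class_histogram["6"]))
  invisible(x)
}
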