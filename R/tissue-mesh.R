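#' Planar polygonal tissue mesh
#'
#' The vertex-model substrate: a planar tessellation in which each cell is a
#' counter-clockwise loop of shared vertices. Interior edges are shared by
#' exactly two cells, boundary edges by one.
#'
#' @param vertices Numeric n x 2 matrix of vertex positions (model length
#'   units, a.u.).
#' @param cells List of integer vectors: ordered vertex-index loops, one per
#'   cell. Loops are re-oriented counter-clockwise if needed.
#' @param validate Check structural invariants (default `TRUE`).
#' @return An object of class `tissue_mesh`.
#' @export
tissue_mesh <- function(vertices, cells, validate = TRUE) {
  vertices <- as.matrix(vertices)
  stopifnot(is.numeric(vertices), ncol(vertices) == 2)
  cells <- lapply(cells, as.integer)
  mesh <- structure(list(vertices = vertices, cells = cells),
                    class = "tissue_mesh")
  # orient all loops CCW
  for (k in seq_along(cells)) {
    xy <- vertices[cells[[k]], , drop = FALSE]
    if (polygon_area(xy) < 0) mesh$cells[[k]] <- rev(cells[[k]])
  }
  if (validate) validate_mesh(mesh)
  mesh
}

validate_mesh <- function(mesh) {
  n <- nrow(mesh$vertices)
  for (k in seq_along(mesh$cells)) {
    cl <- mesh$cells[[k]]
    if (length(cl) < 3) stop("cell ", k, " has fewer than 3 vertices")
    if (anyDuplicated(cl)) stop("cell ", k, " repeats a vertex")
    if (any(cl < 1 | cl > n)) stop("cell ", k, " references missing vertices")
  }
  ed <- mesh_edges(mesh)
  if (any(ed$n_cells > 2)) {
    stop("edge shared by more than 2 cells (non-manifold mesh)")
  }
  invisible(mesh)
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf("Tissue mesh: %d cells, %d vertices, total area %.4g\n",
              length(x$cells), nrow(x$vertices), sum(cell_areas(x))))
  invisible(x)
}

#' Cell geometry of a tissue mesh
#'
#' @param mesh A [tissue_mesh()].
#' @return `cell_areas`: numeric vector of polygon areas; `cell_perimeters`:
#'   perimeters; `cell_centroids`: n_cells x 2 matrix of area centroids.
#' @export
cell_areas <- function(mesh) {
  vapply(mesh$cells, function(cl) {
    polygon_area(mesh$vertices[cl, , drop = FALSE])
  }, numeric(1))
}

#' @rdname cell_areas
#' @export
cell_perimeters <- function(mesh) {
  vapply(mesh$cells, function(cl) {
    polygon_perimeter(mesh$vertices[cl, , drop = FALSE])
  }, numeric(1))
}

#' @rdname cell_areas
#' @export
cell_centroids <- function(mesh) {
  t(vapply(mesh$cells, function(cl) {
    polygon_centroid(mesh$vertices[cl, , drop = FALSE])
  }, numeric(2)))
}

# Edge table: one row per undirected edge, with incidence count.
mesh_edges <- function(mesh) {
  a <- unlist(mesh$cells, use.names = FALSE)
  b <- unlist(lapply(mesh$cells, function(cl) cl[c(2:length(cl), 1)]),
              use.names = FALSE)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi)
  cnt <- table(key)
  first <- !duplicated(key)
  data.frame(a = lo[first], b = hi[first],
             n_cells = as.integer(cnt[key[first]]))
}

# Per-cell neighbour counts (cells sharing at least one edge) and a flag for
# cells that own a boundary edge.
mesh_neighbours <- function(mesh) {
  nc <- length(mesh$cells)
  cell_of <- rep(seq_len(nc), lengths(mesh$cells))
  a <- unlist(mesh$cells, use.names = FALSE)
  b <- unlist(lapply(mesh$cells, function(cl) cl[c(2:length(cl), 1)]),
              use.names = FALSE)
  key <- paste(pmin(a, b), pmax(a, b))
  sp <- split(cell_of, key)
  n_nb <- integer(nc)
  on_boundary <- logical(nc)
  for (cells_on_edge in sp) {
    if (length(cells_on_edge) == 2) {
      n_nb[cells_on_edge[1]] <- n_nb[cells_on_edge[1]] + 1L
      n_nb[cells_on_edge[2]] <- n_nb[cells_on_edge[2]] + 1L
    } else {
      on_boundary[cells_on_edge[1]] <- TRUE
    }
  }
  data.frame(cell = seq_len(nc), n_neighbours = n_nb, boundary = on_boundary)
}

# Flattened slot representation used by the force code and the C++ engine.
# One slot per (cell, vertex) incidence; 0-based companion copy for C++.
mesh_slots <- function(mesh) {
  cells <- mesh$cells
  sv <- unlist(cells, use.names = FALSE)
  len <- lengths(cells)
  scell <- rep(seq_along(cells), len)
  svnext <- unlist(lapply(cells, function(cl) cl[c(2:length(cl), 1)]),
                   use.names = FALSE)
  svprev <- unlist(lapply(cells, function(cl) cl[c(length(cl), 1:(length(cl) - 1))]),
                   use.names = FALSE)
  # edge multiplicity: interior (2 slots) vs boundary (1 slot)
  key <- paste(pmin(sv, svnext), pmax(sv, svnext))
  mult <- as.integer(table(key)[key])
  list(sv = sv, svnext = svnext, svprev = svprev, scell = scell,
       edge_mult = mult, edge_key = key)
}

# t1 reference length: default threshold is 1% of the mean edge length
mean_edge_length <- function(mesh) {
  sl <- mesh_slots(mesh)
  d <- mesh$vertices[sl$svnext, , drop = FALSE] - mesh$vertices[sl$sv, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  # interior edges appear twice; a simple mean over slots is fine here
  mean(len)
}
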