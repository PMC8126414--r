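# vertex-model energy and forces

test_that("energy vanishes for a relaxed configuration with zero tension", {
  # regular hexagon at its target area/perimeter, gamma = 0
  s <- sqrt(2 / (3 * sqrt(3)))
  ang <- pi / 6 + (0:5) * pi / 3
  mesh <- tissue_mesh(cbind(s * cos(ang), s * sin(ang)), list(1:6))
  st <- data.frame(cell = 1, target_area = 1, age = 0, cycle_duration = 10,
                   division_area_threshold = 4, proliferative = FALSE)
  C_hex <- 6 * s
  p <- vertex_params(gamma_cc = 0, gamma_boundary = 0,
                     target_shape = C_hex / sqrt(1))
  u <- potential_energy(mesh, st, p)
  expect_equal(u$total, 0, tolerance = 1e-12)
})

test_that("a unit square with area target 2 has pure area energy lambda*(1-2)^2", {
  mesh <- tissue_mesh(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), list(1:4))
  st <- data.frame(cell = 1, target_area = 2, age = 0, cycle_duration = 10,
                   division_area_threshold = 4, proliferative = FALSE)
  p <- vertex_params(lambda_area = 1, beta_perimeter = 0, gamma_cc = 0,
                     gamma_boundary = 0)
  expect_equal(potential_energy(mesh, st, p)$total, 1, tolerance = 1e-12)
})

test_that("energy agrees with an independent term-by-term summation", {
  hc <- perturbed_honeycomb(16, seed = 4)
  p <- vertex_params()
  u <- potential_energy(hc$mesh, hc$states, p)
  o <- oracle_vm_energy(hc$mesh, hc$states, p)
  expect_equal(u$total, o$total, tolerance = 1e-10)
  expect_equal(u$area, o$area, tolerance = 1e-10)
  expect_equal(u$perimeter, o$perimeter, tolerance = 1e-10)
  expect_equal(u$line, o$line, tolerance = 1e-10)
})

test_that("analytic forces match central finite differences of the energy", {
  for (seed in c(2, 9)) {
    hc <- perturbed_honeycomb(16, seed = seed)
    p <- vertex_params(force_unit = 1)
    F <- vm_forces(hc$mesh, hc$states, p)
    eps <- 1e-6
    set.seed(seed)
    for (i in sample(nrow(hc$mesh$vertices), 6)) {
      for (j in 1:2) {
        m1 <- hc$mesh; m1$vertices[i, j] <- m1$vertices[i, j] + eps
        m2 <- hc$mesh; m2$vertices[i, j] <- m2$vertices[i, j] - eps
        fd <- -(potential_energy(m1, hc$states, p)$total -
                  potential_energy(m2, hc$states, p)$total) / (2 * eps)
        expect_equal(F[i, j], fd,
                     tolerance = 1e-6 * max(1, abs(fd)))
      }
    }
  }
})

test_that("the compiled force engine is numerically identical to the R reference", {
  hc <- perturbed_honeycomb(36, seed = 13)
  hc$states$age <- runif(36, 0, 5)
  p <- vertex_params(boundary_force = 1, force_unit = 1)
  Fr <- vm_forces(hc$mesh, hc$states, p, engine = "r")
  Fc <- vm_forces(hc$mesh, hc$states, p, engine = "cpp")
  expect_equal(Fc, Fr, tolerance = 1e-12)
})

test_that("external boundary forces sum to n_vertices * f per differentiated row", {
  hc <- make_honeycomb(49, 1, seed = 1)
  p <- vertex_params(boundary_force = 1, force_unit = 1,
                     lambda_area = 0, beta_perimeter = 0, gamma_cc = 0,
                     gamma_boundary = 0)
  # relaxed mesh with all elastic terms off: only external forces remain
  hc$states$age <- 0
  F <- vm_forces(hc$mesh, hc$states, p)
  ctr <- cell_centroids(hc$mesh)
  top_cells <- which(!hc$states$proliferative &
                       ctr[, 2] > mean(ctr[, 2]))
  vtop <- unique(unlist(hc$mesh$cells[top_cells]))
  expect_equal(sum(F[, 2][F[, 2] > 0]), length(vtop))
  expect_equal(sum(F[, 2]), 0, tolerance = 1e-12)  # antisymmetric loading
})

test_that("a force-balanced honeycomb with no external force stays put", {
  # request the natural aspect of the 7x7 layout so the hexagons are regular
  hc <- make_honeycomb(49, 11 / (7.5 * sqrt(3)), seed = 2)
  hc$states$age <- 0  # identical targets everywhere
  p <- vertex_params(force_unit = 1)
  F <- vm_forces(hc$mesh, hc$states, p)
  # interior vertices are in equilibrium by symmetry (boundary vertices feel
  # the free edge tension)
  ed <- table(c(unlist(hc$mesh$cells)))
  interior <- as.integer(names(ed)[ed == 3])
  expect_lt(max(abs(F[interior, ])), 1e-8)
})

test_that("degenerate zero-area cells are reported by id", {
  mesh <- tissue_mesh(cbind(c(0, 1, 2, 1), c(0, 0, 0, 0)), list(1:4),
                      validate = FALSE)
  st <- data.frame(cell = 1, target_area = 1, age = 0, cycle_duration = 10,
                   division_area_threshold = 4, proliferative = TRUE)
  expect_error(potential_energy(mesh, st, vertex_params()), "degenerate")
})
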