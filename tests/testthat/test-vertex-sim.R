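# trajectory-level statistics of the vertex model

fake_traj <- function(c0, c1) {
  structure(list(snapshots = list(
    list(time = 0, cells = data.frame(origin = seq_len(nrow(c0)),
                                      x = c0[, 1], y = c0[, 2])),
    list(time = 1, cells = data.frame(origin = seq_len(nrow(c1)),
                                      x = c1[, 1], y = c1[, 2]))
  )), class = "vm_trajectory")
}

test_that("outgrowth bias is 1 for isotropic scaling and tracks affine stretches", {
  set.seed(8)
  c0 <- cbind(runif(40), runif(40))
  expect_equal(compute_outgrowth_bias(fake_traj(c0, 1.7 * c0)), 1,
               tolerance = 1e-12)
  c1 <- cbind(c0[, 1], 2 * c0[, 2])
  expect_equal(compute_outgrowth_bias(fake_traj(c0, c1)), 2,
               tolerance = 1e-12)
  c2 <- cbind(1.2 * c0[, 1], 2.4 * c0[, 2])
  expect_equal(compute_outgrowth_bias(fake_traj(c0, c2)), 2,
               tolerance = 1e-12)
  expect_error(compute_outgrowth_bias(list(fake_traj(c0, c0)$snapshots[[1]])),
               "2 snapshots")
})

test_that("division-angle histograms normalize and bin as stated", {
  rec <- data.frame(division_angle = c(10, 10, 80))
  h <- division_angle_histogram(rec, 30)
  expect_equal(as.numeric(h), c(2 / 3, 0, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(h), 1)
  expect_error(division_angle_histogram(rec[0, , drop = FALSE]), "no division")
  expect_error(division_angle_histogram(rec, 25), "divisible")
})

test_that("population-SD convention: areas {1,1,4} give CV sqrt(2)able", {
  # population sd of (1,1,4) = sqrt(2), mean = 2 -> CV = sqrt(2)/2
  v <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1),
             c(2, 0), c(2, 1),
             c(4, 0), c(4, 2), c(2, 2))
  cells <- list(c(1, 2, 3, 4), c(2, 5, 6, 3), c(5, 7, 8, 9))
  mesh <- tissue_mesh(v, cells)
  st <- shape_statistics(mesh)
  expect_equal(st$area_cv, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(sum(st$polygon_class_histogram), 1, tolerance = 1e-12)
})

test_that("rigid translation and pure stretch give the stated displacement profiles", {
  set.seed(9)
  c0 <- cbind(runif(30), runif(30, 0, 2))
  shift <- cbind(c0[, 1], c0[, 2] + 3)
  dp <- displacement_profile(fake_traj(c0, shift))
  expect_equal(dp$rel_displacement, rep(1, 30), tolerance = 1e-12)
  ctr <- mean(c0[, 2])
  stretch <- cbind(c0[, 1], ctr + 2 * (c0[, 2] - ctr))
  dp2 <- displacement_profile(fake_traj(c0, stretch))
  expect_gt(cor(dp2$rel_displacement, dp2$y0)^2, 1 - 1e-9)
  expect_false(is.unsorted(dp2$y0))
})

test_that("unforced non-dividing tissue stays isotropic (bias ~ 1)", {
  p <- vertex_params(seed = 2, duration = 4, boundary_force = 0,
                     cycle_mean = 1e6, div_area_mean = 1e6)
  traj <- run_simulation(p, n_cells = 49, snapshot_every = 2)
  expect_equal(traj$stats$elongation_bias, 1, tolerance = 0.02)
  expect_equal(traj$stats$n_divisions, 0)
})
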