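# tube-collapse scenarios (fuller runs live in test-acceptance.R)

test_that("clamped tubes reach a mirror-symmetric equilibrium with localized stress", {
  mat <- material_params()
  res <- simulate_collapse(ring_mesh(100), mat, load_scenario("clamps"),
                           collapse_control(max_time = 800))
  expect_true(res$converged)
  x <- res$nodes
  # mirror symmetry about both clamp axes (x and y), node-wise
  n <- nrow(x)
  flip_y <- cbind(x[, 1], -x[, 2])
  d <- vapply(seq_len(n), function(i) {
    min(sqrt((flip_y[, 1] - x[i, 1])^2 + (flip_y[, 2] - x[i, 2])^2))
  }, numeric(1))
  expect_lt(max(d), 1e-3)
  flip_x <- cbind(-x[, 1], x[, 2])
  d2 <- vapply(seq_len(n), function(i) {
    min(sqrt((flip_x[, 1] - x[i, 1])^2 + (flip_x[, 2] - x[i, 2])^2))
  }, numeric(1))
  expect_lt(max(d2), 1e-3)
  # tissue surface respects the clamp gap (2.5 t apart) within 5% of t
  t <- 0.5
  expect_lt(max(abs(x[, 2])), 2.5 * t / 2 - t / 2 + 0.05 * t)
  # hoop stress localized at the two free lobes
  pr <- stress_curvature_profiles(res)
  expect_gt(max(abs(pr$stress_E)) / median(abs(pr$stress_E)), 5)
  # the two dominant stress peaks are antipodal within one node spacing
  top2 <- order(-abs(pr$stress_E))[1:2]
  sep <- abs(diff(pr$arc_length[top2]))
  total <- max(pr$arc_length)
  expect_equal(min(sep, total - sep), total / 2, tolerance = 2 / 100 * total)
})

test_that("profiles of an undeformed circle are uniform and arc-length-periodic", {
  r <- ring_mesh(100)
  res <- list(nodes = r$nodes,
              epsilon = ring_energy(r, material_params())$epsilon,
              kappa = ring_energy(r, material_params())$kappa,
              ring = r, mat = material_params(),
              scenario = load_scenario("pressure"))
  class(res) <- "collapse_result"
  pr <- stress_curvature_profiles(res)
  expect_lt(diff(range(pr$stress_E)), 1e-12)
  expect_equal(pr$kappa_R, rep(pr$kappa_R[1], 100), tolerance = 1e-9)
  expect_equal(nrow(pr), 100)
})

test_that("equilibria converge under mesh refinement (n=100 vs n=200)", {
  mat <- material_params()
  scen <- load_scenario("volume", target_fraction = 0.45, perturbation = 1e-2)
  r100 <- simulate_collapse(ring_mesh(100), mat, scen,
                            collapse_control(max_time = 600))
  r200 <- simulate_collapse(ring_mesh(200), mat, scen,
                            collapse_control(max_time = 600))
  # Hausdorff between the midline CURVES (node-to-polygon distance): a
  # vertex-to-vertex comparison would be floored at half the coarse node
  # spacing (~0.03 R) by discreteness alone
  h12 <- max(epitube:::dist_to_polygon(r100$nodes, r200$nodes))
  h21 <- max(epitube:::dist_to_polygon(r200$nodes, r100$nodes))
  expect_lt(max(h12, h21), 0.01)
})

test_that("total mechanical energy decreases once the ramp stops", {
  mat <- material_params()
  res <- simulate_collapse(ring_mesh(100), mat,
                           load_scenario("volume", target_fraction = 0.45,
                                         perturbation = 1e-2),
                           collapse_control(max_time = 600))
  tr <- as.data.frame(res$trace)
  after <- tr[tr$ramp == 0, ]
  tot <- after$U + after$K
  expect_true(all(diff(tot) < 1e-8 * max(tot)))
})
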