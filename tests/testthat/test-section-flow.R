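# numerical axial-flow solver on polygonal cross-sections

test_that("numerical duct flow matches the elliptical closed form across aspect ratios", {
  cases <- list(c(a = 10, b = 10, res = 150),
                c(a = 20, b = 4, res = 200),
                c(a = 20, b = 2, res = 300),
                c(a = 50, b = 1, res = 1100))
  for (cs in cases) {
    sec <- make_lumen_polygon("ellipse", a = cs["a"], b = cs["b"],
                              n_vertices = 512)
    sol <- solve_cross_section_flow(sec, flow_spec(), resolution = cs["res"])
    ref <- ellipse_wall_shear(elliptical_tube(cs["a"], cs["b"]), flow_spec())
    expect_equal(sol$tau_mean, ref$tau_mean, tolerance = 0.02,
                 label = sprintf("tau_mean at aspect %g", cs["a"] / cs["b"]))
  }
})

test_that("flow through a circle has uniform wall shear (CV < 2%)", {
  sec <- make_lumen_polygon("ellipse", a = 10, b = 10, n_vertices = 512)
  sol <- solve_cross_section_flow(sec, flow_spec(), resolution = 200)
  tau <- sol$boundary$tau
  expect_lt(sd(tau) / mean(tau), 0.02)
})

test_that("the flow rate matches the requested driver (rescaling contract)", {
  sec <- make_lumen_polygon("ellipse", a = 20, b = 5, n_vertices = 256)
  sol <- solve_cross_section_flow(sec, flow_spec(flow_rate = 420),
                                  resolution = 200)
  expect_equal(sol$flow_rate, 420, tolerance = 1e-9)
  sol2 <- solve_cross_section_flow(sec, flow_spec(mean_velocity = 0.364),
                                   resolution = 200)
  expect_equal(sol2$mean_velocity, 0.364, tolerance = 1e-9)
  # u = 0 enforced at the wall, u > 0 inside
  expect_gt(min(sol$u[is.finite(sol$u)]), 0)
})

test_that("wall shear balances the pressure gradient (momentum identity)", {
  # for fully developed flow, mean tau * perimeter = G * area exactly
  sec <- make_lumen_polygon("ellipse", a = 20, b = 4, n_vertices = 512)
  sol <- solve_cross_section_flow(sec, flow_spec(), resolution = 250)
  A <- pi * 20 * 4
  P <- integrate(function(th) sqrt(20^2 * sin(th)^2 + 4^2 * cos(th)^2),
                 0, 2 * pi, rel.tol = 1e-10)$value
  expect_equal(sol$tau_mean, sol$pressure_gradient * A / P, tolerance = 0.02)
})

test_that("under-resolved narrow sections are refused with guidance", {
  sec <- make_lumen_polygon("ellipse", a = 50, b = 1, n_vertices = 256)
  expect_error(solve_cross_section_flow(sec, flow_spec(), resolution = 100),
               "narrowest opening")
})

test_that("rescale_section scales one axis about the centroid", {
  sec <- make_lumen_polygon("ellipse", a = 20, b = 10, n_vertices = 256)
  same <- rescale_section(sec, 1, "y")
  expect_equal(unclass(same), unclass(sec), tolerance = 1e-12)
  narrow <- rescale_section(sec, 0.1, "y")
  expect_equal(diff(range(narrow[, 2])), 2, tolerance = 1e-6)
  expect_equal(diff(range(narrow[, 1])), 40, tolerance = 1e-6)
  expect_equal(shoelace(unclass(narrow)),
               0.1 * shoelace(unclass(sec)), tolerance = 1e-12)
})

test_that("section CSV and GeoJSON-style files round-trip", {
  sec <- make_lumen_polygon("dumbbell", a = 20, b = 5, waist_fraction = 0.3)
  for (ext in c(".csv", ".json")) {
    path <- tempfile(fileext = ext)
    write_section(sec, path)
    sec2 <- read_section(path)
    expect_equal(unclass(sec2), unclass(sec), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})
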