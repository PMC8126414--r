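# synthetic-data generators: honeycombs, lumen polygons, tube image series

test_that("a 100-cell honeycomb has aspect ~1, unit-area cells, hexagonal interior", {
  hc <- make_honeycomb(100, 1, seed = 1)
  expect_length(hc$mesh$cells, 100)
  bb <- apply(hc$mesh$vertices, 2, range)
  aspect <- (bb[2, 2] - bb[1, 2]) / (bb[2, 1] - bb[1, 1])
  expect_gt(aspect, 0.9); expect_lt(aspect, 1.1)
  expect_equal(cell_areas(hc$mesh), rep(1, 100), tolerance = 1e-9)
  st <- shape_statistics(hc$mesh)
  interior <- !st$neighbours$boundary
  expect_true(all(st$neighbours$n_neighbours[interior] == 6))
  # differentiated top and bottom rows exist and never divide
  expect_gt(sum(!hc$states$proliferative), 10)
})

test_that("honeycomb state sampling is deterministic per seed", {
  a <- make_honeycomb(49, 1, seed = 5)
  b <- make_honeycomb(49, 1, seed = 5)
  expect_identical(a, b)
  c <- make_honeycomb(49, 1, seed = 6)
  expect_false(identical(a$states, c$states))
  expect_error(make_honeycomb(8, 1, seed = 1))
})

test_that("lumen polygons have the requested geometry", {
  circ <- make_lumen_polygon("ellipse", a = 1, b = 1, n_vertices = 4096)
  expect_equal(shoelace(unclass(circ)), pi, tolerance = 1e-3)
  slit <- make_lumen_polygon("ellipse", a = 20, b = 1)
  expect_equal(diff(range(slit[, 2])), 2, tolerance = 1e-9)
  expect_equal(shoelace(unclass(slit)), pi * 20, tolerance = 1e-3 * pi * 20)
})

test_that("dumbbell lumens have a waist flanked by two width maxima", {
  db <- make_lumen_polygon("dumbbell", a = 20, b = 5, waist_fraction = 0.3,
                           n_vertices = 720)
  xy <- unclass(db)
  xs <- seq(-15, 15, by = 0.5)
  width <- vapply(xs, function(x0) {
    ys <- xy[abs(xy[, 1] - x0) < 1, 2]
    diff(range(ys))
  }, numeric(1))
  ctr <- which.min(abs(xs))
  left <- which.max(width[seq_len(ctr)])
  right <- ctr + which.max(width[ctr:length(xs)]) - 1
  expect_lt(width[ctr], width[left])
  expect_lt(width[ctr], width[right])
  expect_lt(left, ctr); expect_gt(right, ctr)
})

test_that("tube image series carries exact relative ground truth", {
  ts <- make_tube_image_series(length_growth = 2, width_growth = 0.8,
                               n_frames = 5)
  gt <- ts$ground_truth
  expect_equal(gt$rel_length[5], 2, tolerance = 1e-9)
  expect_equal(gt$rel_width[5], 0.8, tolerance = 1e-9)
  # zero growth: identical frames
  ts0 <- make_tube_image_series(length_growth = 1, width_growth = 1,
                                n_frames = 3)
  expect_identical(ts0$masks[[1]], ts0$masks[[3]])
})

test_that("tube series round-trips through TIFF", {
  ts <- make_tube_image_series(n_frames = 3)
  path <- tempfile(fileext = ".tif")
  write_tube_series(ts, path, "masks")
  back <- read_tube_series(path)
  expect_length(back, 3)
  expect_equal(back[[2]] > 0.5, ts$masks[[2]], ignore_attr = TRUE)
})

test_that("sub-pixel widths and canvas bounds are enforced", {
  expect_error(make_tube_image_series(width0 = 3), ">= 4 px")
})
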