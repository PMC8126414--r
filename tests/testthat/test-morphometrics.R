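# skeleton-based branch morphometrics

test_that("a straight bar skeletonizes to a single axial path with its true width", {
  fr <- binary_frame(bar_mask(), 1)
  sk <- skeletonize_mask(fr)
  g <- extract_branch_graph(sk, 1)
  expect_length(g$branches, 1)
  expect_equal(sum(g$nodes$type == "junction"), 0)
  # the path is horizontal (single row)
  expect_equal(length(unique(g$branches[[1]]$path[, 1])), 1)
  w <- measure_branch_widths(fr, g)
  expect_equal(as.vector(w), 10, tolerance = 1)
})

test_that("a bare 1-px path has length (n-1) steps; diagonals count sqrt(2)", {
  m <- matrix(FALSE, 20, 120)
  m[10, 11:110] <- TRUE
  g <- extract_branch_graph(m, 1)
  expect_equal(g$branches[[1]]$length_um, 99)
  d <- matrix(FALSE, 120, 120)
  d[cbind(11:110, 11:110)] <- TRUE
  gd <- extract_branch_graph(d, 1)
  expect_equal(gd$branches[[1]]$length_um, 99 * sqrt(2), tolerance = 1e-9)
  # um scaling
  g2 <- extract_branch_graph(m, 1.3)
  expect_equal(g2$branches[[1]]$length_um, 99 * 1.3)
})

test_that("a plus-shaped mask yields one junction, four branches, four endpoints", {
  p <- matrix(FALSE, 61, 61)
  p[29:33, 6:56] <- TRUE
  p[6:56, 29:33] <- TRUE
  fr <- binary_frame(p, 1)
  g <- extract_branch_graph(skeletonize_mask(fr), 1)
  expect_equal(sum(g$nodes$type == "junction"), 1)
  expect_length(g$branches, 4)
  expect_equal(sum(g$nodes$type == "endpoint"), 4)
})

test_that("a disc reduces to a degenerate central branch of width ~2r", {
  fr <- binary_frame(disc_mask(15), 1)
  g <- extract_branch_graph(skeletonize_mask(fr), 1)
  w <- measure_branch_widths(fr, g)
  expect_equal(max(w), 30, tolerance = 2)
})

test_that("a synthetic Y-tube gives 3 branches, 1 junction, 3 endpoints", {
  m <- matrix(FALSE, 120, 120)
  # vertical trunk and two arms drawn as thick lines
  thick <- function(m, r0, c0, r1, c1, w) {
    n <- 200
    rr <- round(seq(r0, r1, length.out = n))
    cc <- round(seq(c0, c1, length.out = n))
    for (i in seq_len(n)) {
      m[max(1, rr[i] - w):min(nrow(m), rr[i] + w),
        max(1, cc[i] - w):min(ncol(m), cc[i] + w)] <- TRUE
    }
    m
  }
  m <- thick(m, 110, 60, 60, 60, 4)
  m <- thick(m, 60, 60, 15, 25, 4)
  m <- thick(m, 60, 60, 15, 95, 4)
  fr <- binary_frame(m, 1)
  g <- extract_branch_graph(skeletonize_mask(fr), 1)
  expect_equal(sum(g$nodes$type == "junction"), 1)
  expect_length(g$branches, 3)
  expect_equal(sum(g$nodes$type == "endpoint"), 3)
})

test_that("centerline length of a curved synthetic tube is recovered within 3%", {
  ts <- make_tube_image_series(n_frames = 2)
  fr <- binary_frame(ts$masks[[1]], ts$pixel_size)
  g <- extract_branch_graph(skeletonize_mask(fr), ts$pixel_size)
  len <- max(vapply(g$branches, `[[`, numeric(1), "length_um"))
  expect_equal(len, ts$ground_truth$length_um[1], tolerance = 0.03)
})

test_that("a tapered tube's mean width lies between its end widths, near the true mean", {
  m <- matrix(FALSE, 60, 220)
  for (c0 in 11:210) {
    w <- 20 - 10 * (c0 - 11) / 199       # width 20 px -> 10 px
    m[round(30 - w / 2):round(30 + w / 2), c0] <- TRUE
  }
  fr <- binary_frame(m, 1)
  g <- extract_branch_graph(skeletonize_mask(fr), 1)
  w <- max(measure_branch_widths(fr, g))
  expect_gt(w, 10); expect_lt(w, 20)
  expect_equal(w, 15, tolerance = 0.1 * 15)
})

test_that("preprocess recovers a noise-free synthetic mask within a 1-px band", {
  ts <- make_tube_image_series(n_frames = 2, noise = 0)
  img <- ts$images[[1]]
  fr <- preprocess(img, ts$pixel_size,
                   params = list(clahe_nx = 0, bg_radius = 0, blur_sigma = 1))
  truth <- ts$masks[[1]]
  # disagreement only within 1 px of the true boundary
  edt_in <- as.matrix(EBImage::distmap(EBImage::Image(truth * 1)))
  edt_out <- as.matrix(EBImage::distmap(EBImage::Image((!truth) * 1)))
  band <- (edt_in <= 1.5 & truth) | (edt_out <= 1.5 & !truth)
  expect_true(all(fr$mask == truth | band))
  # inverted-contrast involution
  fr_inv <- preprocess(1 - img, ts$pixel_size,
                       params = list(clahe_nx = 0, bg_radius = 0,
                                     blur_sigma = 1, invert = TRUE))
  expect_equal(fr_inv$mask, fr$mask)
  expect_error(preprocess(matrix(0, 10, 10), 1,
                          params = list(clahe_nx = 0, bg_radius = 0,
                                        blur_sigma = 0)),
               "foreground")
})

test_that("static series track identically; growing series recover (2.0, 0.8) and bias 2.5", {
  ts0 <- make_tube_image_series(length_growth = 1, width_growth = 1,
                                n_frames = 2)
  an0 <- lapply(ts0$masks, function(m) analyze_frame(binary_frame(m, 1)))
  tr0 <- track_branches(an0)
  expect_equal(tr0$table$rel_length, c(1, 1), tolerance = 1e-12)
  expect_equal(tr0$table$rel_width, c(1, 1), tolerance = 1e-12)

  ts <- make_tube_image_series(length_growth = 2, width_growth = 0.8,
                               n_frames = 5)
  an <- lapply(ts$masks, function(m) analyze_frame(binary_frame(m, 1)))
  tr <- track_branches(an)
  tab <- tr$table[tr$table$lineage == 1, ]
  expect_equal(tab$rel_length[nrow(tab)], 2.0, tolerance = 0.05)
  expect_equal(tab$rel_width[nrow(tab)], 0.8, tolerance = 0.05)
  expect_equal(elongation_bias_2d(tr), 2.5, tolerance = 0.05)
})

test_that("monotone growth is recovered monotonically after median filtering", {
  ts <- make_tube_image_series(length_growth = 1.8, width_growth = 1,
                               n_frames = 7)
  an <- lapply(ts$masks, function(m) analyze_frame(binary_frame(m, 1)))
  tr <- track_branches(an)
  rl <- tr$table$rel_length[tr$table$lineage == 1]
  smoothed <- stats::runmed(rl, 3)
  expect_false(is.unsorted(smoothed))
})

test_that("a bifurcation keeps the parent lineage and spawns children at the junction frame", {
  ts <- make_tube_image_series(branching = TRUE, n_frames = 5)
  an <- lapply(ts$masks, function(m) analyze_frame(binary_frame(m, 1)))
  tr <- track_branches(an)
  tab <- tr$table
  # parent lineage spans all frames
  expect_equal(sort(unique(tab$frame[tab$lineage == 1])), 1:5)
  # children appear at the branching frame with the parent recorded
  bf <- ts$ground_truth$branch_start_frame + 1  # junction splits the skeleton
  kids <- unique(tab$lineage[tab$frame == bf & tab$lineage != 1])
  expect_gte(length(kids), 2)
  expect_true(all(!is.na(tab$parent[tab$lineage %in% kids])))
})

test_that("relative-bias arithmetic is exact on stated track values", {
  tab <- data.frame(lineage = 1, frame = 1:2, rel_length = c(1, 2),
                    rel_width = c(1, 0.8))
  expect_equal(elongation_bias_2d(tab), 2.5, tolerance = 1e-12)
  iso <- data.frame(lineage = 1, frame = 1:2, rel_length = c(1, 1.5),
                    rel_width = c(1, 1.5))
  expect_equal(elongation_bias_2d(iso), 1, tolerance = 1e-12)
})

test_that("measurements are robust to rotation and pixel-size changes", {
  # 30-degree rotated bar: length and width within 5%
  m <- matrix(FALSE, 160, 160)
  th <- 30 * pi / 180
  for (s in seq(0, 99, by = 0.25)) {
    r0 <- 40 + s * sin(th); c0 <- 20 + s * cos(th)
    m[round(r0 + (-5:5) * cos(th)), round(c0 - (-5:5) * sin(th))] <- TRUE
  }
  fr <- binary_frame(m, 1)
  g <- extract_branch_graph(skeletonize_mask(fr), 1)
  len <- max(vapply(g$branches, `[[`, numeric(1), "length_um"))
  w <- max(measure_branch_widths(fr, g))
  expect_equal(len, 99, tolerance = 0.06)
  expect_equal(w, 10.8, tolerance = 0.08)  # drawn cross-section ~11 px
  # doubling the pixel size: um outputs within 3%
  ts <- make_tube_image_series(n_frames = 2, pixel_size = 1)
  t2 <- make_tube_image_series(n_frames = 2, pixel_size = 2)
  g1 <- analyze_frame(binary_frame(ts$masks[[1]], 1))
  g2 <- analyze_frame(binary_frame(t2$masks[[1]], 2))
  l1 <- max(vapply(g1$graph$branches, `[[`, numeric(1), "length_um"))
  l2 <- max(vapply(g2$graph$branches, `[[`, numeric(1), "length_um"))
  expect_equal(l2, l1, tolerance = 0.03)
  expect_equal(max(g2$widths_um), max(g1$widths_um), tolerance = 0.06)
})
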