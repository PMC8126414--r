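# shared fixtures, built in code at test time

shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# small perturbed honeycomb for gradient checks
perturbed_honeycomb <- function(n = 16, seed = 2, amp = 0.02) {
  hc <- make_honeycomb(n, 1, seed = seed)
  set.seed(seed + 100)
  hc$mesh$vertices <- hc$mesh$vertices +
    matrix(rnorm(length(hc$mesh$vertices), 0, amp), ncol = 2)
  hc
}

# independent term-by-term vertex-model energy (oracle; loops, no shared code
# with the vectorized/compiled force path)
oracle_vm_energy <- function(mesh, states, params) {
  U_A <- 0; U_C <- 0
  grow <- ifelse(states$proliferative,
                 1 + states$age / states$cycle_duration, 1)
  A0 <- states$target_area * grow
  C0 <- params$target_shape * sqrt(A0)
  for (k in seq_along(mesh$cells)) {
    xy <- mesh$vertices[mesh$cells[[k]], , drop = FALSE]
    n <- nrow(xy)
    A <- 0; C <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      A <- A + (xy[i, 1] * xy[j, 2] - xy[j, 1] * xy[i, 2]) / 2
      C <- C + sqrt(sum((xy[j, ] - xy[i, ])^2))
    }
    U_A <- U_A + params$lambda_area * (A - A0[k])^2
    U_C <- U_C + params$beta_perimeter * (C - C0[k])^2
  }
  # edges once each
  seen <- character(0)
  U_L <- 0
  for (k in seq_along(mesh$cells)) {
    cl <- mesh$cells[[k]]
    n <- length(cl)
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      key <- paste(min(cl[i], cl[j]), max(cl[i], cl[j]))
      if (key %in% seen) next
      seen <- c(seen, key)
    }
  }
  # classify edges by incidence count
  all_a <- unlist(mesh$cells)
  all_b <- unlist(lapply(mesh$cells, function(cl) cl[c(2:length(cl), 1)]))
  key <- paste(pmin(all_a, all_b), pmax(all_a, all_b))
  cnt <- table(key)
  for (kk in names(cnt)) {
    ab <- as.integer(strsplit(kk, " ")[[1]])
    len <- sqrt(sum((mesh$vertices[ab[1], ] - mesh$vertices[ab[2], ])^2))
    gam <- if (cnt[[kk]] == 2) params$gamma_cc else params$gamma_boundary
    U_L <- U_L + gam * len
  }
  list(total = U_A + U_C + U_L, area = U_A, perimeter = U_C, line = U_L)
}

# independent term-by-term ring energy oracle
oracle_ring_energy <- function(ring, mat) {
  x <- ring$nodes
  n <- nrow(x)
  t <- ring$thickness
  U_s <- 0; U_b <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    len <- sqrt(sum((x[j, ] - x[i, ])^2))
    eps <- (len - ring$rest_lengths[i]) / ring$rest_lengths[i]
    U_s <- U_s + mat$E_star * t / 2 * eps^2 * ring$rest_lengths[i]
  }
  for (i in seq_len(n)) {
    im <- if (i == 1) n else i - 1
    ip <- if (i == n) 1 else i + 1
    e1 <- x[i, ] - x[im, ]
    e2 <- x[ip, ] - x[i, ]
    a1 <- atan2(e1[2], e1[1]); a2 <- atan2(e2[2], e2[1])
    dth <- a2 - a1
    dth <- atan2(sin(dth), cos(dth))
    s <- (ring$rest_lengths[im] + ring$rest_lengths[i]) / 2
    U_b <- U_b + mat$E_star * t^3 / 24 * (dth / s)^2 * s
  }
  U_s + U_b
}

# simple rasterized shapes
bar_mask <- function(nr = 30, nc = 120, rows = 11:20, cols = 11:110) {
  m <- matrix(FALSE, nr, nc)
  m[rows, cols] <- TRUE
  m
}

disc_mask <- function(r = 15, pad = 6) {
  n <- 2 * (r + pad) + 1
  ctr <- r + pad + 1
  m <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    m[i, ] <- (i - ctr)^2 + (seq_len(n) - ctr)^2 <= r^2
  }
  m
}
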