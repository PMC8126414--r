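#' Discretized epithelial ring (tube cross-section midline)
#'
#' The tube-collapse substrate: the closed tissue midline of a tube
#' cross-section, discretized into straight segments, with a constant
#' (thickness-preserving) tissue thickness. Rest lengths are the segment
#' lengths of the initial circle, so the undeformed ring is stress-free in
#' stretch; the tissue is intrinsically uncurved (a stress-free
#' configuration would be flat), so the circular midline carries a baseline
#' bending energy.
#'
#' @param n Number of segments along the circumference (default 100).
#' @param radius Initial midline radius R (length unit of the model).
#' @param thickness Tissue thickness t; default `0.5 * radius`.
#' @return Object of class `ring_mesh`: list with `nodes` (n x 2, CCW),
#'   `rest_lengths`, `thickness`, `radius`.
#' @export
ring_mesh <- function(n = 100, radius = 1, thickness = 0.5 * radius) {
  stopifnot(n >= 8, radius > 0, thickness > 0)
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  nodes <- cbind(radius * cos(th), radius * sin(th))
  seg <- nodes[c(2:n, 1), , drop = FALSE] - nodes
  structure(list(nodes = nodes, rest_lengths = sqrt(rowSums(seg^2)),
                 thickness = thickness, radius = radius),
            class = "ring_mesh")
}

#' @export
print.ring_mesh <- function(x, ...) {
  cat(sprintf("Ring mesh: %d segments, R = %g, t = %g (t/R = %g)\n",
              nrow(x$nodes), x$radius, x$thickness, x$thickness / x$radius))
  invisible(x)
}

#' Material parameters of the tissue continuum
#'
#' Linearly elastic, isotropic tissue: Young's modulus `E` sets the energy
#' scale; Poisson's ratio enters through the effective plane-strain modulus
#' \eqn{E^* = E/(1-\nu^2)}; `rho` is the (homogeneous) mass density and
#' `tau_relax` the viscous relaxation time defining the damping matrix
#' `D = M / tau_relax`.
#'
#' @param E Young's modulus (> 0).
#' @param nu Poisson's ratio in `[0, 0.5)`; default 0.49 (nearly
#'   incompressible tissue).
#' @param rho Mass density per unit area.
#' @param tau_relax Viscous relaxation time (> 0).
#' @return Object of class `material_params`.
#' @export
material_params <- function(E = 1, nu = 0.49, rho = 1, tau_relax = 1) {
  stopifnot(E > 0, nu >= 0, nu < 0.5, rho > 0, tau_relax > 0)
  structure(list(E = E, nu = nu, rho = rho, tau_relax = tau_relax,
                 E_star = E / (1 - nu^2)),
            class = "material_params")
}

# signed turning angles and discrete geometry of a closed loop
ring_geometry <- function(nodes, rest_lengths) {
  n <- nrow(nodes)
  e <- nodes[c(2:n, 1), , drop = FALSE] - nodes       # edge i: node i -> i+1
  len <- sqrt(rowSums(e^2))
  if (any(len < 1e-14)) stop("zero segment length in ring")
  phi <- atan2(e[, 2], e[, 1])
  ep <- rbind(e[n, ], e[-n, , drop = FALSE])          # edge ending at node i
  lenp <- c(len[n], len[-n])
  dphi <- phi - c(phi[n], phi[-n])
  theta <- atan2(sin(dphi), cos(dphi))                # wrap to (-pi, pi]
  s_rest <- (c(rest_lengths[n], rest_lengths[-n]) + rest_lengths) / 2
  s_cur <- (lenp + len) / 2
  list(e = e, len = len, ep = ep, lenp = lenp, theta = theta,
       s_rest = s_rest, s_cur = s_cur)
}

#' Elastic energy of a ring configuration
#'
#' Total two-dimensional stretch-and-bend energy of the tissue
#' cross-section,
#' \deqn{U = \frac{E^* t}{2}\oint \varepsilon^2\, ds
#'       + \frac{E^* t^3}{24}\oint \kappa^2\, ds,}
#' with hoop Cauchy strain \eqn{\varepsilon_i = (\ell_i -
#' \ell_{i,rest})/\ell_{i,rest}} per segment and midline curvature
#' \eqn{\kappa_i} from the turning angle at each node divided by the mean
#' adjacent segment length. The quadrature uses the material (rest) arc
#' measure, so pure stretching does not change the bending energy.
#'
#' @param ring A [ring_mesh()].
#' @param mat A [material_params()].
#' @return List with `total`, `stretch`, `bend`, and per-element `epsilon`
#'   (per segment), `kappa` (per node, signed, current-geometry measure).
#' @export
ring_energy <- function(ring, mat) {
  g <- ring_geometry(ring$nodes, ring$rest_lengths)
  t <- ring$thickness
  eps <- (g$len - ring$rest_lengths) / ring$rest_lengths
  kap_mat <- g$theta / g$s_rest          # material curvature (energy measure)
  U_s <- mat$E_star * t / 2 * sum(eps^2 * ring$rest_lengths)
  U_b <- mat$E_star * t^3 / 24 * sum(kap_mat^2 * g$s_rest)
  list(total = U_s + U_b, stretch = U_s, bend = U_b,
       epsilon = eps, kappa = g$theta / g$s_cur)
}

# analytic elastic forces: -grad U (stretch + bend); vectorized
ring_forces <- function(nodes, rest_lengths, thickness, mat) {
  n <- nrow(nodes)
  g <- ring_geometry(nodes, rest_lengths)
  t <- thickness
  # stretch: tension T_i = E* t eps_i along edge i
  eps <- (g$len - rest_lengths) / rest_lengths
  Tn <- mat$E_star * t * eps
  ehat <- g$e / g$len
  f <- matrix(0, n, 2)
  # edge i pulls node i toward i+1 and node i+1 toward i when stretched
  fe <- ehat * Tn
  f <- f + fe
  f[c(2:n, 1), ] <- f[c(2:n, 1), ] - fe
  # bending: discrete moment m_i = dU/dtheta_i = (E* t^3 / 12) theta_i / s_rest_i
  m <- mat$E_star * t^3 / 12 * g$theta / g$s_rest
  perp <- cbind(-g$e[, 2], g$e[, 1]) / g$len^2        # d(edge angle)/d(head)
  perpp <- cbind(-g$ep[, 2], g$ep[, 1]) / g$lenp^2
  # theta_i = phi(e_i) - phi(e_{i-1});
  # dtheta_i/dx_{i+1} = perp_i, dtheta_i/dx_i = -perp_i - perp_{i-1},
  # dtheta_i/dx_{i-1} = perp_{i-1}
  fb <- matrix(0, n, 2)
  fb[c(2:n, 1), ] <- fb[c(2:n, 1), ] - m * perp
  fb <- fb + m * (perp + perpp)
  fb[c(n, 1:(n - 1)), ] <- fb[c(n, 1:(n - 1)), ] - m * perpp
  f + fb
}

#' Classical buckling pressure of an elastic ring
#'
#' Critical external pressure for collapse of a thin elastic ring,
#' \eqn{P_{cr} = 3 E^* I / R^3} with \eqn{I = t^3/12} and
#' \eqn{E^* = E/(1-\nu^2)}. Used as the analytic anchor for the
#' pressure-collapse simulation.
#'
#' @param mat A [material_params()].
#' @param R Midline radius.
#' @param thickness Tissue thickness.
#' @return Critical pressure (force per unit length per unit tube length).
#' @examples
#' critical_pressure(material_params(E = 1, nu = 0), R = 1, thickness = 0.5)
#' @export
critical_pressure <- function(mat, R, thickness) {
  3 * mat$E_star * thickness^3 / 12 / R^3
}
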