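#' Load scenario for tube collapse
#'
#' Exactly one collapse driver:
#' \describe{
#'   \item{pressure}{A net inward pressure difference, ramped linearly at
#'     `rate` (pressure per unit time) until the enclosed area has dropped
#'     below `collapse_area_fraction` of its initial value (the tube has
#'     collapsed), then held constant while the shape equilibrates. Buckling
#'     symmetry breaking is seeded by a deterministic mode-2 radial
#'     perturbation of amplitude `perturbation` times R.}
#'   \item{clamps}{Two rigid parallel horizontal walls approach at constant
#'     `speed` until they are `final_gap_thickness` tissue thicknesses
#'     apart, then stop.}
#'   \item{volume}{The enclosed (lumen) area is driven linearly from its
#'     initial value to `target_fraction` of it over `drain_time`, then
#'     held. The constraint is a stiff penalty whose stiffness keeps the
#'     volume error below 0.5%.}
#' }
#'
#' @param kind `"pressure"`, `"clamps"` or `"volume"`.
#' @param rate Pressure ramp rate (pressure / tau).
#' @param max_pressure Optional cap on the ramped pressure.
#' @param collapse_area_fraction Area fraction at which the pressure ramp
#'   stops.
#' @param speed Clamp approach speed (R / tau).
#' @param final_gap_thickness Final wall separation in units of thickness.
#' @param target_fraction Final enclosed-area fraction for drainage.
#' @param drain_time Drainage duration (tau).
#' @param perturbation Relative amplitude of the seeded mode-2 perturbation
#'   (pressure scenario only).
#' @return Object of class `load_scenario`.
#' @export
load_scenario <- function(kind = c("pressure", "clamps", "volume"),
                          rate = NULL, max_pressure = NULL,
                          collapse_area_fraction = 0.4,
                          speed = 0.05, final_gap_thickness = 2.5,
                          target_fraction = 0.2, drain_time = 25,
                          perturbation = 1e-4) {
  kind <- match.arg(kind)
  structure(list(kind = kind, rate = rate, max_pressure = max_pressure,
                 collapse_area_fraction = collapse_area_fraction,
                 speed = speed, final_gap_thickness = final_gap_thickness,
                 target_fraction = target_fraction, drain_time = drain_time,
                 perturbation = perturbation),
            class = "load_scenario")
}

#' Numerical controls for the collapse integrator
#'
#' @param cfl Time-step safety factor against the stiffest elastic mode.
#' @param tol_speed Equilibrium tolerance on the maximum nodal speed
#'   (R / tau units).
#' @param tol_force Equilibrium tolerance on the net nodal force (E t units).
#' @param max_time Hard cap on simulated time (tau).
#' @param contact_stiffness_scale Penalty contact stiffness in units of
#'   `E * t` per unit length.
#' @param record_every Sampling interval (tau) of the energy/diagnostic
#'   trace.
#' @return List of class `collapse_control`.
#' @export
collapse_control <- function(cfl = 0.35, tol_speed = 1e-5, tol_force = 1e-5,
                             max_time = 2000, contact_stiffness_scale = 40,
                             record_every = 0.5) {
  list(cfl = cfl, tol_speed = tol_speed, tol_force = tol_force,
       max_time = max_time, contact_stiffness_scale = contact_stiffness_scale,
       record_every = record_every)
}

#' Simulate the collapse of an epithelial tube cross-section
#'
#' Integrates Newton's second law \eqn{M\ddot x + D\dot x = f(x, t)} for the
#' discrete ring with a second-order explicit Newmark scheme in
#' predictor-corrector form (lumped mass matrix, damping `D = M/tau`).
#' `f` collects elastic stretch/bend forces, the scenario load (follower
#' pressure on the current edges, rigid-wall penalty contact, or the area
#' penalty), and penalty self-contact that keeps opposite tube walls from
#' approaching closer than the tissue thickness. Integration continues
#' after the load ramp stops until static equilibrium (maximum nodal speed
#' and residual force below tolerance).
#'
#' @param ring A [ring_mesh()].
#' @param mat A [material_params()].
#' @param scenario A [load_scenario()].
#' @param control A [collapse_control()].
#' @return Object of class `collapse_result`: `nodes` (equilibrium
#'   positions), `epsilon`, `stress` (hoop stress in units of E),
#'   `kappa` (signed midline curvature), `enclosed_area`, `scenario`,
#'   `load` (final pressure / gap / area target), `trace` (time series of
#'   energy and max speed), `converged`.
#' @export
simulate_collapse <- function(ring, mat, scenario,
                              control = collapse_control()) {
  stopifnot(inherits(ring, "ring_mesh"), inherits(mat, "material_params"),
            inherits(scenario, "load_scenario"))
  n <- nrow(ring$nodes)
  x <- ring$nodes
  t_thick <- ring$thickness
  R <- ring$radius
  lr <- ring$rest_lengths

  if (scenario$kind %in% c("pressure", "volume")) {
    # deterministic mode-2 seed so the buckling plane is reproducible; the
    # cos(2*theta) mode is mirror-symmetric about both axes
    th <- atan2(x[, 2], x[, 1])
    r0 <- sqrt(rowSums(x^2))
    r0 <- r0 * (1 + scenario$perturbation * cos(2 * th))
    x <- cbind(r0 * cos(th), r0 * sin(th))
  }

  A0 <- polygon_area(x)
  P_cr <- critical_pressure(mat, R, t_thick)
  rate <- scenario$rate
  if (is.null(rate)) rate <- P_cr / 25
  p_max <- scenario$max_pressure
  if (is.null(p_max)) p_max <- 3 * P_cr

  # lumped mass and damping
  s_node <- (c(lr[n], lr[-n]) + lr) / 2
  m_node <- mat$rho * t_thick * s_node
  d_node <- m_node / mat$tau_relax

  # stable explicit time step from the stiffest stretch/bend/contact mode;
  # re-estimated periodically because segments compress as the tube folds
  k_c <- control$contact_stiffness_scale * mat$E_star * t_thick
  stable_dt <- function(lmin) {
    k_est <- 2 * mat$E_star * t_thick / lmin +
      4 * mat$E_star * t_thick^3 / 12 / lmin^3 + k_c * max(s_node)
    control$cfl * 2 / sqrt(k_est / min(m_node))
  }
  dt <- stable_dt(min(lr))

  # clamp state
  wall <- max(abs(x[, 2])) + t_thick / 2 + 0.05 * R  # wall y-position (+/-)
  final_wall <- scenario$final_gap_thickness * t_thick / 2

  # self-contact exclusion: nodes closer than ~2.5 t along the loop
  excl <- max(3L, ceiling(2.5 * t_thick / mean(lr)))

  force_fun <- function(x, time, ramping) {
    f <- ring_forces(x, lr, t_thick, mat)
    load <- list()
    if (scenario$kind == "pressure") {
      P <- min(rate * time, p_max)
      if (!ramping$ramp_on) P <- ramping$p_final
      e <- x[c(2:n, 1), , drop = FALSE] - x
      fp <- P * cbind(-e[, 2], e[, 1])      # inward on a CCW loop
      f <- f + fp / 2
      f[c(2:n, 1), ] <- f[c(2:n, 1), ] + fp / 2
      load$pressure <- P
    } else if (scenario$kind == "clamps") {
      w <- max(final_wall, wall - scenario$speed * time)
      over_top <- x[, 2] + t_thick / 2 - w
      over_bot <- -w - (x[, 2] - t_thick / 2)
      fy <- numeric(n)
      fy[over_top > 0] <- -k_c * over_top[over_top > 0]
      fy[over_bot > 0] <- fy[over_bot > 0] + k_c * over_bot[over_bot > 0]
      f[, 2] <- f[, 2] + fy * s_node
      load$gap <- 2 * w
    } else {
      frac <- 1 - (1 - scenario$target_fraction) *
        min(time / scenario$drain_time, 1)
      A_t <- A0 * frac
      A <- polygon_area(x)
      kV <- 2000 * mat$E_star * t_thick / R^2   # volume error << 0.5%
      coef <- -kV * (A - A_t)
      xp <- x[c(2:n, 1), , drop = FALSE]
      xm <- x[c(n, 1:(n - 1)), , drop = FALSE]
      f <- f + 0.5 * coef * cbind(xp[, 2] - xm[, 2], xm[, 1] - xp[, 1])
      load$area_target <- A_t
    }
    # penalty self-contact between distant-in-index node pairs
    ct <- ring_self_contact(x, t_thick, k_c, s_node, excl)
    f + ct
  }

  v <- matrix(0, n, 2)
  a <- matrix(0, n, 2)
  time <- 0
  ramping <- list(ramp_on = TRUE, p_final = NA_real_)
  trace <- list()
  next_rec <- 0
  converged <- FALSE
  vmax_scale <- R / mat$tau_relax
  fscale <- mat$E * t_thick

  step_count <- 0L
  while (time < control$max_time) {
    step_count <- step_count + 1L
    if (step_count %% 50L == 0L) {
      cur <- sqrt(rowSums((x[c(2:n, 1), , drop = FALSE] - x)^2))
      dt <- stable_dt(min(cur))
    }
    # Newmark predictor (beta = 0, gamma = 1/2)
    x <- x + dt * v + dt^2 / 2 * a
    v_star <- v + dt / 2 * a
    time <- time + dt
    f <- force_fun(x, time, ramping)
    a <- (f - d_node * v_star) / (m_node + dt / 2 * d_node)
    v <- v_star + dt / 2 * a
    if (!all(is.finite(x)) || !all(is.finite(f))) {
      g <- ring_geometry(x, lr)
      stop("collapse integration diverged at t = ", signif(time, 4),
           " (min segment ", signif(min(g$len), 3),
           ", reduce cfl or ramp rate)")
    }

    # ramp termination per scenario
    if (ramping$ramp_on) {
      if (scenario$kind == "pressure") {
        if (polygon_area(x) < scenario$collapse_area_fraction * A0 ||
            rate * time >= p_max) {
          ramping <- list(ramp_on = FALSE, p_final = min(rate * time, p_max))
        }
      } else if (scenario$kind == "clamps") {
        if (wall - scenario$speed * time <= final_wall) {
          ramping$ramp_on <- FALSE
        }
      } else if (time >= scenario$drain_time) {
        ramping$ramp_on <- FALSE
      }
    }

    if (time >= next_rec) {
      # full potential: elastic + load/constraint/contact penalty terms, so
      # the energy audit sees every reservoir
      en <- ring_energy_at(x, lr, t_thick, mat)
      A_now <- polygon_area(x)
      if (scenario$kind == "pressure") {
        P_now <- if (ramping$ramp_on) min(rate * time, p_max) else
          ramping$p_final
        en <- en + P_now * A_now
      } else if (scenario$kind == "clamps") {
        w <- max(final_wall, wall - scenario$speed * time)
        ot <- pmax(0, x[, 2] + t_thick / 2 - w)
        ob <- pmax(0, -w - (x[, 2] - t_thick / 2))
        en <- en + sum(k_c * s_node / 2 * (ot^2 + ob^2))
      } else {
        frac <- 1 - (1 - scenario$target_fraction) *
          min(time / scenario$drain_time, 1)
        kV <- 2000 * mat$E_star * t_thick / R^2
        en <- en + kV / 2 * (A_now - A0 * frac)^2
      }
      en <- en + ring_contact_energy(x, t_thick, k_c, s_node, excl)
      ke <- sum(0.5 * m_node * rowSums(v^2))
      rad <- sqrt(rowSums(x^2))
      trace[[length(trace) + 1L]] <-
        c(time = time, U = en, K = ke,
          vmax = max(sqrt(rowSums(v^2))),
          area = polygon_area(x),
          deviation = (max(rad) - min(rad)) / 2,
          pressure = if (scenario$kind == "pressure") {
            if (ramping$ramp_on) min(rate * time, p_max) else ramping$p_final
          } else NA_real_,
          ramp = as.numeric(ramping$ramp_on))
      next_rec <- next_rec + control$record_every
    }

    if (!ramping$ramp_on) {
      vmax <- max(sqrt(rowSums(v^2)))
      fmax <- max(sqrt(rowSums(f^2))) / pmax(s_node, 1e-300)[1]
      if (vmax < control$tol_speed * vmax_scale &&
          max(sqrt(rowSums(f^2)) / s_node) < control$tol_force * fscale) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged) {
    stop(sprintf(paste0("collapse simulation did not reach equilibrium ",
                        "within max_time: max speed %.3g R/tau, ",
                        "max residual %.3g E*t"),
                 max(sqrt(rowSums(v^2))) / vmax_scale,
                 max(sqrt(rowSums(f^2))) / fscale))
  }

  rr <- list(nodes = x, rest_lengths = lr, thickness = t_thick, radius = R)
  class(rr) <- "ring_mesh"
  en <- ring_energy(rr, mat)
  structure(list(
    nodes = x,
    epsilon = en$epsilon,
    stress = mat$E_star / mat$E * en$epsilon,
    kappa = en$kappa,
    enclosed_area = polygon_area(x),
    scenario = scenario,
    load = ramping,
    ring = rr, mat = mat,
    trace = do.call(rbind, trace),
    converged = converged
  ), class = "collapse_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ring_energy_at <- function(x, lr, t_thick, mat) {
  rr <- list(nodes = x, rest_lengths = lr, thickness = t_thick, radius = NA)
  class(rr) <- "ring_mesh"
  ring_energy(rr, mat)$total
}

ring_contact_energy <- function(x, t_thick, k_c, s_node, excl) {
  n <- nrow(x)
  d2 <- outer(x[, 1], x[, 1], "-")^2 + outer(x[, 2], x[, 2], "-")^2
  idx <- abs(outer(seq_len(n), seq_len(n), "-"))
  idx <- pmin(idx, n - idx)
  cand <- which(d2 < t_thick^2 & idx > excl, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (!nrow(cand)) return(0)
  ov <- t_thick - sqrt(d2[cand])
  sum(k_c * s_node[cand[, 1]] / 2 * ov^2)
}

# repulsive penalty between non-adjacent nodes closer than the thickness
ring_self_contact <- function(x, t_thick, k_c, s_node, excl) {
  n <- nrow(x)
  f <- matrix(0, n, 2)
  dx <- outer(x[, 1], x[, 1], "-")
  dy <- outer(x[, 2], x[, 2], "-")
  d2 <- dx * dx + dy * dy
  idx <- abs(outer(seq_len(n), seq_len(n), "-"))
  idx <- pmin(idx, n - idx)
  cand <- which(d2 < t_thick^2 & idx > excl, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  if (!nrow(cand)) return(f)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    d <- sqrt(d2[i, j])
    if (d < 1e-12) next
    push <- k_c * (t_thick - d) * s_node[i]
    ux <- dx[i, j] / d; uy <- dy[i, j] / d
    f[i, ] <- f[i, ] + push * c(ux, uy)
    f[j, ] <- f[j, ] - push * c(ux, uy)
  }
  f
}

#' Buckling pressure from a pressure-collapse trace
#'
#' Under a slowly ramped pressure, the seeded non-circularity of the ring
#' decays as long as the pressure is subcritical and starts to grow once it
#' exceeds the buckling threshold; the pressure at the turning point of the
#' radial deviation therefore estimates the critical pressure. Compare with
#' [critical_pressure()].
#'
#' @param result A `collapse_result` from a pressure scenario.
#' @return Estimated buckling pressure.
#' @export
buckling_pressure <- function(result) {
  stopifnot(inherits(result, "collapse_result"),
            result$scenario$kind == "pressure")
  tr <- as.data.frame(result$trace)
  tr <- tr[tr$ramp == 1, , drop = FALSE]
  if (nrow(tr) < 3) stop("trace too short to locate the buckling onset")
  tr$pressure[which.min(tr$deviation)]
}

#' Arc-length profiles of hoop stress and curvature
#'
#' Samples the equilibrated collapse result at its nodes: arc length from
#' node 1, hoop strain, hoop stress in units of Young's modulus E, and the
#' dimensionless midline curvature `kappa * R`.
#'
#' @param result A `collapse_result`.
#' @return Data frame: `arc_length`, `x`, `y`, `epsilon`, `stress_E`,
#'   `kappa_R`.
#' @export
stress_curvature_profiles <- function(result) {
  stopifnot(inherits(result, "collapse_result"))
  x <- result$nodes
  n <- nrow(x)
  seg <- sqrt(rowSums((x[c(2:n, 1), , drop = FALSE] - x)^2))
  arc <- c(0, cumsum(seg[-n]))
  # per-node strain: mean of adjacent segment strains
  eps_node <- (result$epsilon + c(result$epsilon[n], result$epsilon[-n])) / 2
  data.frame(arc_length = arc, x = x[, 1], y = x[, 2],
             epsilon = eps_node,
             stress_E = result$mat$E_star / result$mat$E * eps_node,
             kappa_R = result$kappa * result$ring$radius)
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf("Collapse result (%s): area %.3g (%.0f%% of circle), converged: %s\n",
              x$scenario$kind, x$enclosed_area,
              100 * x$enclosed_area / (pi * x$ring$radius^2), x$converged))
  cat(sprintf("  |stress|/E max %.3g | |kappa R| max %.3g\n",
              max(abs(x$stress)), max(abs(x$kappa * x$ring$radius))))
  invisible(x)
}
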