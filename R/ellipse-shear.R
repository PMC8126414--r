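#' Elliptical tube cross-section
#'
#' Constructs an elliptical lumen cross-section from its semi-axes. Lengths
#' are in micrometres throughout.
#'
#' @param a Semi-major axis (µm).
#' @param b Semi-minor axis (µm). Must satisfy `a >= b > 0`.
#' @return An object of class `elliptical_tube`.
#' @examples
#' elliptical_tube(50, 1)
#' @export
elliptical_tube <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1, length(b) == 1)
  if (!(a >= b && b > 0)) {
    stop("need a >= b > 0 (semi-major >= semi-minor > 0)")
  }
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = "elliptical_tube")
}

#' @export
print.elliptical_tube <- function(x, ...) {
  cat(sprintf("Elliptical tube cross-section: a = %g um, b = %g um (aspect %g)\n",
              x$a, x$b, x$a / x$b))
  invisible(x)
}

#' Flow specification for fully developed lumen flow
#'
#' Defines the fluid viscosity and exactly one flow driver: either the
#' cross-section mean axial velocity or the volumetric flow rate. The default
#' viscosity corresponds to embryonic lung luminal fluid, ten times that of
#' water; the default mean velocity is the bead-derived estimate for E11.5
#' mouse lung.
#'
#' @param viscosity Dynamic viscosity µ (Pa·s). Default 0.016.
#' @param mean_velocity Cross-section average axial velocity (µm/s).
#' @param flow_rate Volumetric flow rate (µm³/s). Supply at most one of
#'   `mean_velocity` / `flow_rate`; if neither is given, the default mean
#'   velocity 0.364 µm/s is used.
#' @return An object of class `flow_spec`.
#' @examples
#' flow_spec()                      # 0.016 Pa·s, 0.364 um/s
#' flow_spec(flow_rate = 420)      # driven by flow rate instead
#' @export
flow_spec <- function(viscosity = 0.016, mean_velocity = NULL, flow_rate = NULL) {
  stopifnot(is.numeric(viscosity), length(viscosity) == 1, viscosity > 0)
  if (!is.null(mean_velocity) && !is.null(flow_rate)) {
    stop("supply exactly one of 'mean_velocity' or 'flow_rate'")
  }
  if (is.null(mean_velocity) && is.null(flow_rate)) {
    mean_velocity <- 0.364
  }
  if (!is.null(mean_velocity) && mean_velocity <= 0) stop("mean_velocity must be > 0")
  if (!is.null(flow_rate) && flow_rate <= 0) stop("flow_rate must be > 0")
  structure(list(viscosity = viscosity,
                 mean_velocity = if (is.null(mean_velocity)) NULL else as.numeric(mean_velocity),
                 flow_rate = if (is.null(flow_rate)) NULL else as.numeric(flow_rate)),
            class = "flow_spec")
}

# Mean velocity implied by a flow_spec on an ellipse (u_bar = Vdot / (pi a b)).
spec_mean_velocity <- function(spec, tube) {
  if (!is.null(spec$mean_velocity)) spec$mean_velocity
  else spec$flow_rate / (pi * tube$a * tube$b)
}

#' Wall shear stress of Hagen-Poiseuille flow in an elliptical tube
#'
#' Closed-form wall shear stress for steady, fully developed laminar axial
#' flow in a tube of elliptical cross-section. The axial velocity profile is
#' \deqn{u(y, z) = u_{max} (1 - y^2/a^2 - z^2/b^2), \quad u_{max} = 2\bar u,}
#' and the wall shear magnitude at boundary angle \eqn{\theta} (with the wall
#' point at \eqn{(a\cos\theta, b\sin\theta)}) is
#' \deqn{\tau(\theta) = 2 \mu u_{max} \sqrt{\cos^2\theta/a^2 + \sin^2\theta/b^2}.}
#' Shear is maximal at the minor-axis co-vertices (the flat side of a
#' collapsed lumen) and minimal at the major-axis vertices (the strongly
#' curved ends). The reported mean is the arc-length-weighted boundary
#' average, computed by adaptive quadrature.
#'
#' @param tube An [elliptical_tube()].
#' @param spec A [flow_spec()].
#' @param n_theta Number of sample angles for the returned profile.
#' @return A list of class `wall_shear_profile` with elements `theta`, `tau`
#'   (Pa), `tau_mean`, `tau_max`, `tau_min`, `u_max`, `mean_velocity`,
#'   `flow_rate`.
#' @examples
#' # collapsed E11.5 lung lumen: 2 um opening, high aspect
#' ellipse_wall_shear(elliptical_tube(50, 1), flow_spec())$tau_mean
#' @export
ellipse_wall_shear <- function(tube, spec = flow_spec(), n_theta = 720) {
  stopifnot(inherits(tube, "elliptical_tube"), inherits(spec, "flow_spec"))
  a <- tube$a; b <- tube$b
  u_bar <- spec_mean_velocity(spec, tube)
  u_max <- 2 * u_bar
  mu <- spec$viscosity

  tau_fun <- function(theta) {
    2 * mu * u_max * sqrt(cos(theta)^2 / a^2 + sin(theta)^2 / b^2)
  }
  ds_fun <- function(theta) sqrt(a^2 * sin(theta)^2 + b^2 * cos(theta)^2)

  # arc-length-weighted mean over one quadrant (profile has 4-fold symmetry)
  num <- stats::integrate(function(th) tau_fun(th) * ds_fun(th), 0, pi / 2,
                          rel.tol = 1e-10)$value
  den <- stats::integrate(ds_fun, 0, pi / 2, rel.tol = 1e-10)$value

  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  structure(list(
    theta = theta,
    tau = tau_fun(theta),
    tau_mean = num / den,
    tau_max = 2 * mu * u_max / b,
    tau_min = 2 * mu * u_max / a,
    u_max = u_max,
    mean_velocity = u_bar,
    flow_rate = pi * a * b * u_bar
  ), class = "wall_shear_profile")
}

#' @export
print.wall_shear_profile <- function(x, ...) {
  cat(sprintf("Wall shear stress profile: mean %.3g Pa, max %.3g Pa, min %.3g Pa\n",
              x$tau_mean, x$tau_max, x$tau_min))
  cat(sprintf("  mean velocity %.3g um/s, flow rate %.3g um^3/s\n",
              x$mean_velocity, x$flow_rate))
  invisible(x)
}
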