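#' Bead tracks
#'
#' A set of particle tracks from lumen flow velocimetry: per-track time
#' series of 2D positions (µm) with strictly increasing timestamps (s).
#'
#' @param df Data frame with columns `track_id`, `t_s`, `x_um`, `y_um`.
#' @return An object of class `bead_tracks` (the validated data frame).
#' @export
bead_tracks <- function(df) {
  need <- c("track_id", "t_s", "x_um", "y_um")
  if (!all(need %in% names(df))) {
    stop("tracks need columns: ", paste(need, collapse = ", "))
  }
  df <- df[order(df$track_id, df$t_s), , drop = FALSE]
  n_per <- table(df$track_id)
  if (any(n_per < 2)) stop("every track needs >= 2 points")
  dup <- unlist(tapply(df$t_s, df$track_id, function(t) any(diff(t) <= 0)))
  if (any(dup)) stop("timestamps must be strictly increasing within a track")
  structure(df, class = c("bead_tracks", "data.frame"))
}

#' Maximum track speed and mean-velocity estimate from bead tracks
#'
#' Per-track speed is the maximum over consecutive-point displacements
#' divided by the time interval (the maximum-track-speed read-out used for
#' injected beads). The fastest observed bead gives a lower bound on the
#' true peak flow velocity; under a parabolic (Poiseuille) profile the
#' cross-section mean velocity is half the peak, so the mean-velocity
#' estimate is `u_max_observed / 2`.
#'
#' @param tracks A [bead_tracks()] object or a data frame coercible to one.
#' @param smooth If `TRUE`, apply a 3-point running mean to positions before
#'   differencing (for noisy tracks). Default `FALSE`.
#' @return List with `u_max_observed` (µm/s), `u_bar_estimate` (µm/s), and
#'   `per_track` (data frame of per-track max speeds).
#' @examples
#' df <- data.frame(track_id = 1, t_s = 0:3,
#'                  x_um = 0, y_um = 0.73 * (0:3))
#' mean_velocity_from_tracks(df)
#' @export
mean_velocity_from_tracks <- function(tracks, smooth = FALSE) {
  if (!inherits(tracks, "bead_tracks")) tracks <- bead_tracks(tracks)
  ids <- unique(tracks$track_id)
  speed <- vapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, , drop = FALSE]
    x <- tr$x_um; y <- tr$y_um
    if (smooth && nrow(tr) >= 3) {
      x <- stats::filter(x, rep(1 / 3, 3), sides = 2)
      y <- stats::filter(y, rep(1 / 3, 3), sides = 2)
      keep <- !is.na(x)
      x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
      t <- tr$t_s[keep]
    } else {
      t <- tr$t_s
    }
    if (length(x) < 2) return(0)
    max(sqrt(diff(x)^2 + diff(y)^2) / diff(t))
  }, numeric(1))
  per_track <- data.frame(track_id = ids, max_speed = speed)
  moving <- speed[speed > 0]
  if (!length(moving)) stop("all tracks are stationary; no velocity estimate")
  u_max <- max(moving)
  list(u_max_observed = u_max,
       u_bar_estimate = u_max / 2,
       per_track = per_track)
}

#' Generate synthetic bead tracks with a Poiseuille speed profile
#'
#' Seeds beads at random positions inside an elliptical cross-section and
#' advects them axially with the local Poiseuille speed
#' \eqn{u_{max}(1 - y^2/a^2 - z^2/b^2)}; optional isotropic Gaussian
#' positional noise is added to the recorded coordinates. Tracks are emitted
#' in the image plane (x = transverse position across the major axis,
#' y = axial), matching the 2D projection available when imaging a lumen.
#' The fastest emitted track speed never exceeds `u_max`, preserving the
#' lower-bound character of the bead read-out.
#'
#' @param tube An [elliptical_tube()] (µm).
#' @param u_max Peak (centreline) speed, µm/s. The E11.5 lung measurement
#'   is 0.73 µm/s.
#' @param n_beads Number of beads.
#' @param dt Frame interval (s).
#' @param duration Total duration (s).
#' @param noise_sd Positional noise SD (µm).
#' @param seed RNG seed (mandatory).
#' @return List with `tracks` (a [bead_tracks()]) and `ground_truth`
#'   (list: `u_max`, `u_bar = u_max/2`, per-bead true speeds).
#' @export
make_bead_tracks <- function(tube, u_max = 0.73, n_beads = 50, dt = 60,
                             duration = 600, noise_sd = 0, seed) {
  stopifnot(inherits(tube, "elliptical_tube"), u_max > 0, n_beads >= 1)
  if (missing(seed)) stop("'seed' is mandatory for stochastic generators")
  rng <- local({ set.seed(seed); NULL })
  a <- tube$a; b <- tube$b
  # rejection-sample positions uniformly in the ellipse
  ys <- zs <- numeric(0)
  while (length(ys) < n_beads) {
    yy <- stats::runif(2 * n_beads, -a, a)
    zz <- stats::runif(2 * n_beads, -b, b)
    keep <- (yy / a)^2 + (zz / b)^2 < 1
    ys <- c(ys, yy[keep]); zs <- c(zs, zz[keep])
  }
  ys <- ys[seq_len(n_beads)]; zs <- zs[seq_len(n_beads)]
  speed <- u_max * (1 - (ys / a)^2 - (zs / b)^2)

  times <- seq(0, duration, by = dt)
  nt <- length(times)
  df <- data.frame(
    track_id = rep(seq_len(n_beads), each = nt),
    t_s = rep(times, n_beads),
    x_um = rep(ys, each = nt) +
      if (noise_sd > 0) stats::rnorm(n_beads * nt, 0, noise_sd) else 0,
    y_um = rep(speed, each = nt) * rep(times, n_beads) +
      if (noise_sd > 0) stats::rnorm(n_beads * nt, 0, noise_sd) else 0
  )
  list(tracks = bead_tracks(df),
       ground_truth = list(u_max = u_max, u_bar = u_max / 2,
                           bead_speeds = speed, noise_sd = noise_sd,
                           seed = seed))
}
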