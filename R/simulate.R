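#' Elliptical bead orbit
#'
#' The projected orbit of a bead attached to a truncated flagellar
#' filament: an ellipse with centre, semi-axes `a >= b > 0` (nm) and tilt
#' (rotation of the major axis from the x axis, radians).
#'
#' @param a,b semi-major and semi-minor axes, nm (`a >= b > 0`).
#' @param centre numeric length-2, nm (default origin).
#' @param tilt major-axis tilt, radians (default 0).
#' @return an object of class `orbit_ellipse`.
#' @export
orbit_ellipse <- function(a, b, centre = c(0, 0), tilt = 0) {
  check_scalar(a, "a", positive = TRUE)
  check_scalar(b, "b", positive = TRUE)
  check_scalar(tilt, "tilt")
  if (b > a) stop("'a' must be >= 'b'", call. = FALSE)
  if (length(centre) != 2L || !all(is.finite(centre))) {
    stop("'centre' must be two finite numbers", call. = FALSE)
  }
  structure(list(centre = as.numeric(centre), a = as.numeric(a),
                 b = as.numeric(b), tilt = as.numeric(tilt)),
            class = "orbit_ellipse")
}

#' @export
print.orbit_ellipse <- function(x, ...) {
  cat(sprintf(
    "<orbit_ellipse> centre (%.3g, %.3g) nm, a = %.4g, b = %.4g nm, tilt = %.4g rad\n",
    x$centre[1], x$centre[2], x$a, x$b, x$tilt))
  invisible(x)
}

# Point on the ellipse at eccentric angle theta (nm).
ellipse_point <- function(ellipse, theta) {
  ct <- cos(ellipse$tilt); st <- sin(ellipse$tilt)
  u <- ellipse$a * cos(theta)
  v <- ellipse$b * sin(theta)
  cbind(x = ellipse$centre[1] + ct * u - st * v,
        y = ellipse$centre[2] + st * u + ct * v)
}

#' Timed bead trajectory
#'
#' Uniformly sampled bead positions from a rotation assay: times in
#' seconds (strictly increasing), positions in nm.
#'
#' @param t,x,y equal-length numeric vectors (seconds, nm, nm).
#' @return an object of class `bead_trajectory` (a data.frame with columns
#'   `t`, `x`, `y`).
#' @export
bead_trajectory <- function(t, x, y) {
  if (length(t) != length(x) || length(t) != length(y)) {
    stop("'t', 'x' and 'y' must have equal length", call. = FALSE)
  }
  if (length(t) < 1L || !all(is.finite(t)) || !all(is.finite(x)) ||
      !all(is.finite(y))) {
    stop("trajectory columns must be finite and non-empty", call. = FALSE)
  }
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("'t' must be strictly increasing", call. = FALSE)
  }
  structure(data.frame(t = as.numeric(t), x = as.numeric(x),
                       y = as.numeric(y)),
            class = c("bead_trajectory", "data.frame"))
}

#' Simulate a stochastically stepping rotor with an attached bead
#'
#' Emulates a bead-assay recording of a slowly rotating flagellar motor:
#' the rotor dwells on a lattice of `n_steps_per_rev` angles
#' (`phase0 + 2*pi*j/n`), jumps to the next dwell after an exponentially
#' distributed wait (mean `1/step_rate` s; backwards with probability
#' `back_step_prob`), steps are instantaneous, and the bead sits at the
#' orbit-ellipse point of the current dwell angle plus isotropic Gaussian
#' localization noise, sampled at `fps` frames per second.
#'
#' Defaults emulate a slowed (CCCP-treated) motor observed with a
#' high-speed camera: 26 dwells per revolution, 1,000 fps, a step rate
#' giving a 20-frame mean dwell (~2 revolutions per second), a 150 x 90 nm
#' orbit and 20 nm localization noise.
#'
#' @param n_steps_per_rev dwell angles per revolution (integer >= 2).
#' @param step_rate mean stepping rate, steps/s (>= 0; 0 freezes the rotor).
#' @param frames number of frames (integer >= 1).
#' @param fps frame rate, frames/s (> 0).
#' @param orbit an [orbit_ellipse] (nm).
#' @param noise_sd Gaussian localization noise per coordinate, nm (>= 0).
#' @param back_step_prob probability a step is backwards (in `[0, 1)`).
#' @param phase0 angular offset of the dwell lattice, radians.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return a [bead_trajectory] with attributes `theta_true` (ground-truth
#'   dwell angle per frame, radians in `[0, 2*pi)`), `params` and `seed`.
#' @examples
#' traj <- simulate_stepping_trajectory(frames = 2000, seed = 7)
#' @export
simulate_stepping_trajectory <- function(n_steps_per_rev = 26L,
                                         step_rate = 50,
                                         frames = 1e5,
                                         fps = 1000,
                                         orbit = orbit_ellipse(150, 90),
                                         noise_sd = 20,
                                         back_step_prob = 0,
                                         phase0 = 0,
                                         seed = 1L) {
  check_scalar(n_steps_per_rev, "n_steps_per_rev", positive = TRUE,
               integerish = TRUE)
  if (n_steps_per_rev < 2) stop("'n_steps_per_rev' must be >= 2",
                                call. = FALSE)
  check_scalar(step_rate, "step_rate", nonneg = TRUE)
  check_scalar(frames, "frames", positive = TRUE, integerish = TRUE)
  check_scalar(fps, "fps", positive = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(back_step_prob, "back_step_prob", nonneg = TRUE)
  if (back_step_prob >= 1) stop("'back_step_prob' must be < 1", call. = FALSE)
  if (!inherits(orbit, "orbit_ellipse")) {
    stop("'orbit' must be an orbit_ellipse", call. = FALSE)
  }
  frames <- as.integer(frames)
  t <- (seq_len(frames) - 1L) / fps
  duration <- frames / fps
  with_seed(seed, {
    if (step_rate > 0) {
      # draw exponential dwells until the recording is covered
      waits <- numeric(0)
      expected <- step_rate * duration
      repeat {
        k <- ceiling(expected + 10 * sqrt(expected + 1) + 10)
        waits <- c(waits, stats::rexp(k, rate = step_rate))
        if (sum(waits) > duration) break
      }
      jump_t <- cumsum(waits)
      jump_t <- jump_t[jump_t <= duration]
      dirs <- ifelse(stats::runif(length(jump_t)) < back_step_prob, -1L, 1L)
      path <- cumsum(dirs)
      idx_at_frame <- c(0L, path)[findInterval(t, jump_t) + 1L]
    } else {
      idx_at_frame <- rep(0L, frames)
    }
    theta <- wrap_angle(phase0 + 2 * pi * idx_at_frame / n_steps_per_rev)
    p <- ellipse_point(orbit, theta)
    x <- p[, "x"] + stats::rnorm(frames, sd = noise_sd)
    y <- p[, "y"] + stats::rnorm(frames, sd = noise_sd)
    traj <- bead_trajectory(t, x, y)
    attr(traj, "theta_true") <- theta
    attr(traj, "params") <- list(n_steps_per_rev = as.integer(n_steps_per_rev),
                                 step_rate = step_rate, frames = frames,
                                 fps = fps, orbit = orbit,
                                 noise_sd = noise_sd,
                                 back_step_prob = back_step_prob,
                                 phase0 = phase0)
    attr(traj, "seed") <- as.integer(seed)
    traj
  })
}
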