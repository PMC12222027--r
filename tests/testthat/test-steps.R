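test_that("the conic fit recovers a noiseless ellipse to 0.1%", {
  set.seed(21)
  th <- runif(200, 0, 2 * pi)
  truth <- orbit_ellipse(150, 90, centre = c(30, -12), tilt = 0.4)
  p <- flagmotor:::ellipse_point(truth, th)
  fit <- fit_orbit_ellipse(data.frame(x = p[, 1], y = p[, 2]))
  expect_rel_equal(fit$a, 150, tol = 1e-3)
  expect_rel_equal(fit$b, 90, tol = 1e-3)
  expect_lt(abs(fit$tilt - 0.4), 1e-3)
  expect_lt(max(abs(fit$centre - c(30, -12))), 0.1)
})

test_that("the fit is equivariant under translation and handles circles", {
  set.seed(22)
  th <- runif(120, 0, 2 * pi)
  p <- flagmotor:::ellipse_point(orbit_ellipse(150, 90, tilt = 0.7), th)
  f0 <- fit_orbit_ellipse(data.frame(x = p[, 1], y = p[, 2]))
  f1 <- fit_orbit_ellipse(data.frame(x = p[, 1] + 55, y = p[, 2] - 17))
  expect_equal(f1$centre, f0$centre + c(55, -17), tolerance = 1e-6)
  expect_equal(f1$a, f0$a, tolerance = 1e-6)
  pc <- flagmotor:::ellipse_point(orbit_ellipse(100, 100), th)
  fc <- fit_orbit_ellipse(data.frame(x = pc[, 1], y = pc[, 2]))
  expect_rel_equal(fc$a, 100, tol = 1e-6)
  expect_rel_equal(fc$b, 100, tol = 1e-6)
})

test_that("degenerate inputs to the ellipse fit error", {
  expect_error(fit_orbit_ellipse(data.frame(x = 1:5, y = 1:5)),
               "at least 6")
  expect_error(fit_orbit_ellipse(data.frame(x = 1:20, y = 2 * (1:20) + 1)),
               "collinear")
  expect_error(fit_orbit_ellipse(data.frame(x = rep(1, 10), y = rep(2, 10))),
               "coincide")
})

test_that("angle extraction inverts the orbit parametrization", {
  truth <- orbit_ellipse(150, 90, centre = c(10, 5), tilt = 0.4)
  traj <- simulate_stepping_trajectory(orbit = truth, noise_sd = 0,
                                       frames = 3000, seed = 23)
  ang <- trajectory_to_angles(traj, truth)
  th_true <- attr(traj, "theta_true")
  dev <- abs(((ang$theta - th_true + pi) %% (2 * pi)) - pi)
  expect_lt(max(dev), 1e-9)
  # bead fixed at one orbit point: one distinct angle
  frozen <- simulate_stepping_trajectory(step_rate = 0, noise_sd = 0,
                                         frames = 100, seed = 1)
  a2 <- trajectory_to_angles(frozen, orbit_ellipse(150, 90))
  expect_equal(length(unique(a2$theta)), 1L)
})

test_that("frames at the orbit centre are dropped and counted", {
  traj <- bead_trajectory(t = (0:9) / 100,
                          x = c(150, rep(150, 4), 10, rep(150, 4)),
                          y = c(0, rep(0, 4), 5, rep(0, 4)))
  ell <- orbit_ellipse(150, 90, centre = c(10, 5))
  ang <- trajectory_to_angles(traj, ell)
  expect_identical(attr(ang, "dropped_frames"), 1L)
  expect_length(ang$theta, 9)
})

test_that("a uniformly swept orbit gives uniform angles", {
  n <- 1e4
  t <- (seq_len(n) - 1) / 1000
  p <- flagmotor:::ellipse_point(orbit_ellipse(150, 90), 2 * pi * 1.7 * t)
  ang <- trajectory_to_angles(bead_trajectory(t, p[, 1], p[, 2]),
                              orbit_ellipse(150, 90))
  resultant <- Mod(mean(exp(1i * ang$theta)))
  expect_lt(resultant, 0.05)
})

test_that("the wrapped KDE reproduces a single von Mises bump", {
  kappa <- 25
  mu <- 1.3
  prof <- angular_kde(angle_series(rep(mu, 50)), kappa = kappa)
  expected <- exp(kappa * cos(prof$angle - mu)) /
    (2 * pi * besselI(kappa, 0))
  expect_lt(max(abs(prof$density - expected)), 1e-6)
  # unit integral
  expect_equal(sum(prof$density) * 2 * pi / length(prof$density), 1)
})

test_that("the KDE is flat under uniform angles and phase-equivariant", {
  set.seed(24)
  ang <- angle_series(runif(2e4, 0, 2 * pi))
  prof <- angular_kde(ang, kappa = 100)
  # analytic null fluctuation of the estimate
  expect_lt(max(abs(prof$density - 1 / (2 * pi))), 4.5 * prof$se_null)
  # rotating all angles rotates the profile by exactly that amount
  shift_bins <- 37
  shift <- 2 * pi * shift_bins / length(prof$angle)
  prof2 <- angular_kde(angle_series(ang$theta + shift), kappa = 100)
  rotated <- c(prof$density[(1024 - shift_bins + 1):1024],
               prof$density[1:(1024 - shift_bins)])
  expect_lt(max(abs(prof2$density - rotated)), 1e-9)
})

test_that("the angular power spectrum is bounded, phase-invariant and concentrates", {
  set.seed(25)
  # delta distribution: S(k) = 1 for all k
  s1 <- weighted_angular_power_spectrum(angle_series(rep(0.7, 10)), 20)
  expect_equal(s1$power, rep(1, 20))
  # uniform null: S(k) = O(1/n)
  n <- 1e4
  su <- weighted_angular_power_spectrum(angle_series(runif(n, 0, 2 * pi)), 40)
  expect_true(all(su$power >= 0 & su$power <= 1))
  expect_lt(max(su$power), 30 / n)
  # exact phase invariance
  th <- runif(500, 0, 2 * pi)
  w <- runif(500)
  sa <- weighted_angular_power_spectrum(angle_series(th, w), 30)
  sb <- weighted_angular_power_spectrum(angle_series(th + 1.234, w), 30)
  expect_equal(sa$power, sb$power, tolerance = 1e-9)
})

test_that("null spectrum variance scales inversely with sample size", {
  set.seed(26)
  mean_power <- function(n) {
    mean(replicate(30, {
      mean(weighted_angular_power_spectrum(
        angle_series(runif(n, 0, 2 * pi)), 20)$power)
    }))
  }
  p1 <- mean_power(500)
  p2 <- mean_power(4000)
  expect_rel_equal(p1 / p2, 8, tol = 0.35)
})

test_that("the dwell pipeline counts 26 steps and rejects steady rotation", {
  traj <- simulate_stepping_trajectory(frames = 1e5, seed = 1)
  call <- detect_bead_steps(traj)
  expect_identical(call$n_steps_spectral, 26L)
  expect_gt(call$spectral_significance, 70)
  null_call <- detect_bead_steps(steady_rotation_trajectory(seed = 11))
  expect_true(is.na(null_call$n_steps_spectral))
  expect_identical(null_call$n_peaks_kde, 0L)
})

test_that("slow stepping resolves all 26 dwell peaks in the KDE", {
  traj <- simulate_stepping_trajectory(step_rate = 20, frames = 1e5,
                                       seed = 2)
  call <- detect_bead_steps(traj)
  expect_identical(call$n_steps_spectral, 26L)
  expect_identical(call$n_peaks_kde, 26L)
})

test_that("dwell counting is invariant to a global angle offset", {
  traj <- simulate_stepping_trajectory(frames = 4e4, seed = 27)
  ts <- smooth_trajectory(traj, 15)
  ell <- refine_orbit_ellipse(ts, fit_orbit_ellipse(ts))
  ang <- trajectory_to_angles(traj, ell)
  shifted <- angle_series(ang$theta + 0.789, ang$weights, t = ang$t)
  c1 <- count_dwell_positions(ang)
  c2 <- count_dwell_positions(shifted)
  expect_identical(c1$n_steps_spectral, c2$n_steps_spectral)
  expect_equal(c1$spectral_significance, c2$spectral_significance,
               tolerance = 1e-6)
})
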