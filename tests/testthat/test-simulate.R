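test_that("a frozen rotor with no noise never moves", {
  traj <- simulate_stepping_trajectory(step_rate = 0, noise_sd = 0,
                                       frames = 200, seed = 1)
  expect_equal(length(unique(traj$x)), 1L)
  expect_equal(length(unique(traj$y)), 1L)
  # and the bead sits on a dwell point of the orbit
  p <- flagmotor:::ellipse_point(orbit_ellipse(150, 90), 0)
  expect_equal(traj$x[1], p[, "x"][[1]])
})

test_that("trajectories have the requested length and uniform clock", {
  traj <- simulate_stepping_trajectory(frames = 1234, fps = 500, seed = 2)
  expect_equal(nrow(traj), 1234L)
  expect_equal(diff(traj$t), rep(1 / 500, 1233))
  expect_true(all(diff(traj$t) > 0))
})

test_that("dwell angles stay on the n-fold lattice", {
  n <- 13
  traj <- simulate_stepping_trajectory(n_steps_per_rev = n, frames = 5000,
                                       noise_sd = 0, phase0 = 0.3, seed = 3)
  th <- attr(traj, "theta_true")
  lattice_pos <- ((th - 0.3) / (2 * pi / n)) %% n
  expect_lt(max(abs(lattice_pos - round(lattice_pos))), 1e-9)
  expect_gt(length(unique(round(lattice_pos))), 1)
})

test_that("long-run dwell occupancy is uniform", {
  # Frame counts per dwell are not multinomial: each dwell's occupancy is a
  # sum of exponential waits, so the per-dwell total time T_i is
  # Gamma-distributed with variance T_bar * mean_dwell. The correctly
  # scaled statistic sum((T_i - T_bar)^2 / (T_bar * mean_dwell)) is
  # approximately chi-squared with n - 1 degrees of freedom.
  n <- 26; fps <- 1000; rate <- 50
  traj <- simulate_stepping_trajectory(n_steps_per_rev = n, step_rate = rate,
                                       frames = 1e5, fps = fps, seed = 4)
  th <- attr(traj, "theta_true")
  dwell <- round(th / (2 * pi / n)) %% n
  counts <- tabulate(dwell + 1L, n)
  mean_dwell_frames <- fps / rate
  stat <- sum((counts - mean(counts))^2 / (mean(counts) * mean_dwell_frames))
  expect_gt(pchisq(stat, df = n - 1, lower.tail = FALSE), 0.01)
})

test_that("back steps move the rotor backwards on the same lattice", {
  traj <- simulate_stepping_trajectory(n_steps_per_rev = 10, step_rate = 100,
                                       frames = 5000, noise_sd = 0,
                                       back_step_prob = 0.5, seed = 5)
  th <- attr(traj, "theta_true")
  steps <- diff(th[th != c(th[-1], NA)])  # changes only
  lattice_pos <- (th / (2 * pi / 10)) %% 10
  expect_lt(max(abs(lattice_pos - round(lattice_pos))), 1e-9)
})

test_that("simulator rejects invalid parameters", {
  expect_error(simulate_stepping_trajectory(n_steps_per_rev = 1), ">= 2")
  expect_error(simulate_stepping_trajectory(back_step_prob = 1), "< 1")
  expect_error(simulate_stepping_trajectory(frames = 0), "> 0")
})
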