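# Shared fixtures, all generated in code.

# Default ring-phantom geometry used by the property sweeps: radius 120 A,
# sigma 6 A on an 80^3 grid at 4 A/voxel (ring + 3 sigma fits the
# 160 A half-extent for every n).
default_ring_phantom <- function(n, phase0 = 0, amplitude = 1) {
  make_ring_phantom(n, ring_radius = 120, subunit_sigma = 6,
                    grid_shape = 80, voxel_size = 4,
                    phase0 = phase0, amplitude = amplitude)
}

default_ring_band <- c(90, 150)

# Bead circling at constant speed (no steps) with localization noise: the
# null trajectory for step detection.
steady_rotation_trajectory <- function(frames = 2e4, fps = 1000,
                                       rev_per_s = 2, noise_sd = 20,
                                       orbit = orbit_ellipse(150, 90),
                                       seed = 1) {
  set.seed(seed)
  t <- (seq_len(frames) - 1) / fps
  p <- flagmotor:::ellipse_point(orbit, 2 * pi * rev_per_s * t)
  bead_trajectory(t, p[, "x"] + rnorm(frames, sd = noise_sd),
                  p[, "y"] + rnorm(frames, sd = noise_sd))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
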