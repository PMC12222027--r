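test_that("a single blob integrates to the closed-form Gaussian mass", {
  sigma <- 8; amp <- 2.5
  m <- make_ring_phantom(1, ring_radius = 40, subunit_sigma = sigma,
                         grid_shape = 64, voxel_size = 3, amplitude = amp)
  expect_rel_equal(map_total_density(m), amp * (sigma * sqrt(2 * pi))^3,
                   tol = 0.01)
})

test_that("phantom total density scales with blob count", {
  sigma <- 6
  single <- map_total_density(
    make_ring_phantom(1, 120, sigma, 80, 4))
  ring <- map_total_density(default_ring_phantom(17))
  expect_rel_equal(ring, 17 * single, tol = 0.01)
})

test_that("ring phantoms are invariant under rotation by one subunit", {
  for (n in c(5, 17)) {
    m1 <- default_ring_phantom(n)
    m2 <- default_ring_phantom(n, phase0 = 2 * pi / n)
    expect_lt(max(abs(m1$grid - m2$grid)), 0.01 * max(m1$grid))
  }
})

test_that("rings that do not fit the grid are rejected", {
  expect_error(make_ring_phantom(17, 150, 12, 64, 2), "does not fit")
  expect_error(make_cylinder_phantom(100, 40, 20, 64, 2), "does not fit")
})

test_that("generators are deterministic pure functions", {
  a <- default_ring_phantom(11)
  b <- default_ring_phantom(11)
  expect_identical(a$grid, b$grid)
  t1 <- simulate_stepping_trajectory(frames = 500, seed = 42)
  t2 <- simulate_stepping_trajectory(frames = 500, seed = 42)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$y, t2$y)
  t3 <- simulate_stepping_trajectory(frames = 500, seed = 43)
  expect_false(identical(t1$x, t3$x))
})

test_that("a one-ring disk phantom reduces to a ring phantom", {
  model <- disk_lattice_model(R1 = 100, n1 = 13, spacing_ratio = 0.2,
                              n_rings = 1)
  disk <- make_concentric_disk_phantom(model, subunit_sigma = 6,
                                       grid_shape = 80, voxel_size = 4)
  ring <- make_ring_phantom(13, 100, 6, 80, 4)
  expect_equal(disk$grid, ring$grid)
})

test_that("a five-ring disk phantom carries one blob per protomer", {
  model <- disk_lattice_model(R1 = 90, n1 = 51, spacing_ratio = 0.216,
                              n_rings = 5)
  expect_identical(ring_protomer_counts(model), c(51L, 62L, 73L, 84L, 95L))
  sigma <- 4
  disk <- make_concentric_disk_phantom(model, subunit_sigma = sigma,
                                       grid_shape = 128, voxel_size = 3)
  single <- (sigma * sqrt(2 * pi))^3
  expect_rel_equal(map_total_density(disk), 365 * single, tol = 0.01)
})

test_that("the disk phantom's radial profile peaks at every ring radius", {
  model <- disk_lattice_model(R1 = 100, n1 = 51, spacing_ratio = 0.216,
                              n_rings = 3)
  disk <- make_concentric_disk_phantom(model, subunit_sigma = 4,
                                       grid_shape = 128, voxel_size = 3)
  prof <- radial_density_profile(disk, z_band = c(-6, 6))
  for (r in ring_radii(model)) {
    expect_lt(abs(peak_radius(prof, r_window = r + c(-12, 12)) - r), 3)
  }
})

test_that("half maps share the signal, differ in noise, and honour seeds", {
  m <- default_ring_phantom(9)
  hm <- make_half_maps(m, snr = 2, seed = 5)
  hm2 <- make_half_maps(m, snr = 2, seed = 5)
  expect_identical(hm$half1$grid, hm2$half1$grid)
  expect_identical(hm$half2$grid, hm2$half2$grid)
  expect_false(identical(hm$half1$grid, hm$half2$grid))
  hm3 <- make_half_maps(m, snr = 2, seed = 6)
  expect_false(identical(hm$half1$grid, hm3$half1$grid))
  # measured noise variance matches the requested SNR
  noise <- hm$half1$grid - m$grid
  expect_rel_equal(var(as.vector(m$grid)) / var(as.vector(noise)), 2,
                   tol = 0.05)
  # infinite SNR means noise-free copies with unit FSC everywhere
  hmi <- make_half_maps(m, snr = Inf, seed = 1)
  expect_identical(hmi$half1$grid, m$grid)
  fsc <- fsc_curve(hmi$half1, hmi$half2)
  expect_equal(fsc$correlation, rep(1, length(fsc$correlation)))
})
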