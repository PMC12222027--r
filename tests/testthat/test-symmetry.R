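test_that("the azimuthal spectrum peaks at the ring's symmetry order", {
  m <- default_ring_phantom(17)
  s <- azimuthal_power_spectrum(m, default_ring_band, k_max = 60)
  expect_equal(s$harmonics[which.max(s$power)], 17)
})

test_that("the spectrum is invariant to rotation and density scaling", {
  m1 <- default_ring_phantom(13)
  m2 <- default_ring_phantom(13, phase0 = 0.377)  # arbitrary rotation
  s1 <- azimuthal_power_spectrum(m1, default_ring_band, k_max = 40)
  s2 <- azimuthal_power_spectrum(m2, default_ring_band, k_max = 40)
  expect_lt(max(abs(s1$power - s2$power)) / max(s1$power), 0.01)
  m3 <- density_map(5.5 * m1$grid, m1$voxel_size)
  expect_identical(detect_cyclic_symmetry(m3, default_ring_band)$n_fold, 13L)
})

test_that("symmetry detection recovers every order from 2 to 41", {
  for (n in 2:41) {
    call <- detect_cyclic_symmetry(default_ring_phantom(n),
                                   default_ring_band, k_range = 2:60)
    expect_identical(call$n_fold, as.integer(n))
  }
})

test_that("azimuthally uniform and pure-noise maps yield no symmetry call", {
  cyl <- make_cylinder_phantom(62, 60, 6, 128, 2)
  call <- detect_cyclic_symmetry(cyl, c(40, 90), k_range = 2:40)
  expect_true(is.na(call$n_fold))
  set.seed(33)
  noise <- density_map(array(rnorm(48^3), c(48, 48, 48)), 4)
  call2 <- detect_cyclic_symmetry(noise, c(80, 92), k_range = 2:60)
  expect_true(is.na(call2$n_fold))
})

test_that("band and harmonic-limit violations error", {
  m <- default_ring_phantom(7)
  expect_error(azimuthal_power_spectrum(m, c(500, 600)), "band")
  expect_error(azimuthal_power_spectrum(m, c(10, 150), k_max = 60),
               "Nyquist")
})

test_that("imposing C1 is the identity and imposing C_n is idempotent", {
  m <- make_ring_phantom(17, 60, 10, 48, 4)
  expect_identical(impose_cyclic_symmetry(m, 1)$grid, m$grid)
  imp <- impose_cyclic_symmetry(m, 17)
  expect_lt(max(abs(imp$grid - m$grid)), 0.05 * max(m$grid))
})

test_that("imposing C17 on a single blob builds a 17-fold ring", {
  blob <- make_ring_phantom(1, 120, 8, 80, 4)
  ring <- impose_cyclic_symmetry(blob, 17)
  call <- detect_cyclic_symmetry(ring, default_ring_band, k_range = 2:30)
  expect_identical(call$n_fold, 17L)
})

test_that("symmetrization and lathing conserve total density", {
  m <- default_ring_phantom(9)
  expect_rel_equal(sum(impose_cyclic_symmetry(m, 9)$grid), sum(m$grid),
                   tol = 0.005)
  expect_rel_equal(sum(cylindrical_average(m)$grid), sum(m$grid),
                   tol = 0.005)
})

test_that("the lathe matches the discrete C360 rotation oracle", {
  m <- make_ring_phantom(17, 60, 8, 48, 4)
  lat <- cylindrical_average(m)
  oracle <- impose_cyclic_symmetry(m, 360)
  expect_lt(max(abs(lat$grid - oracle$grid)), 0.01 * max(m$grid))
})

test_that("lathing is idempotent and preserves cylinders", {
  cyl <- make_cylinder_phantom(40, 40, 6, 48, 3)
  lat <- cylindrical_average(cyl)
  expect_lt(max(abs(lat$grid - cyl$grid)), 0.05 * max(cyl$grid))
  again <- cylindrical_average(lat)
  expect_lt(max(abs(again$grid - lat$grid)), 0.05 * max(lat$grid))
})

test_that("radial profiles locate cylinder walls to sub-voxel accuracy", {
  cyl62 <- make_cylinder_phantom(62, 60, 6, 128, 2)
  prof <- radial_density_profile(cyl62, z_band = c(-20, 20))
  expect_lt(abs(peak_radius(prof) - 62), 1)  # half a voxel
  cyl51 <- make_cylinder_phantom(51, 60, 6, 128, 2)
  expect_lt(abs(peak_radius(radial_density_profile(cyl51)) - 51), 1)
})

test_that("peak-radius ratios reproduce relative ring widths", {
  a <- make_cylinder_phantom(100, 40, 5, 128, 2)
  b <- make_cylinder_phantom(103, 40, 5, 128, 2)
  ratio <- peak_radius(radial_density_profile(b)) /
    peak_radius(radial_density_profile(a))
  expect_rel_equal(ratio, 1.03, tol = 0.005)
})

test_that("a flat map has no defined peak radius", {
  flat <- density_map(array(1, c(16, 16, 16)), 2)
  prof <- radial_density_profile(flat)
  expect_error(peak_radius(prof), "constant")
  expect_error(radial_density_profile(flat, z_band = c(100, 200)),
               "z_band")
})
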