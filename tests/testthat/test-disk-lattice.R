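test_that("arc spacing follows the circumference formula", {
  expect_equal(arc_spacing(100, 1), 2 * pi * 100)
  expect_equal(arc_spacing(180, 51), 2 * pi * 180 / 51)
  expect_rel_equal(arc_spacing(180, 51), 22.17, tol = 5e-4)
  expect_equal(arc_spacing(360, 51), 2 * arc_spacing(180, 51))
  expect_error(arc_spacing(-1, 10), "> 0")
})

test_that("the packaged disk geometry adds 11 protomers per ring", {
  m <- disk_lattice_model(n1 = 51, spacing_ratio = 0.216, n_rings = 5)
  expect_identical(ring_protomer_counts(m), c(51L, 62L, 73L, 84L, 95L))
  expect_identical(protomer_increment(m), 11L)
  m1 <- disk_lattice_model(n1 = 51, n_rings = 1)
  expect_identical(ring_protomer_counts(m1), 51L)
  expect_error(protomer_increment(m1), "at least 2")
})

test_that("ring counts agree with the brute-force packing oracle", {
  # oracle: the largest n for which the per-protomer arc 2*pi*R_i/n is at
  # least s * (1 - 1/(2n)), found by direct search
  packing_oracle <- function(R_i, s) {
    n <- 1L
    while (2 * pi * R_i / (n + 1L) >= s * (1 - 0.5 / (n + 1L))) n <- n + 1L
    n
  }
  set.seed(101)
  for (i in 1:1000) {
    m <- disk_lattice_model(R1 = runif(1, 50, 400),
                            n1 = sample(3:80, 1),
                            spacing_ratio = runif(1, 0.05, 0.5),
                            n_rings = sample(1:8, 1))
    counts <- ring_protomer_counts(m)
    s <- arc_spacing(m$R1, m$n1)
    oracle <- vapply(ring_radii(m), packing_oracle, integer(1), s = s)
    expect_identical(counts, oracle)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("asymmetric-unit totals multiply out", {
  expect_identical(asu_total(17, 3), 51L)
  expect_identical(asu_total(17, 7), 119L)
  expect_identical(asu_total(1, 9), 9L)
  for (c_ in c(2, 7, 17)) {
    for (m_ in c(1, 3, 8)) {
      expect_identical(asu_total(c_ * m_, 1), asu_total(c_, m_))
    }
  }
})

test_that("symmetry mismatch reports gcd and coincidence period", {
  mm <- symmetry_mismatch(17, 26)
  expect_identical(mm$gcd, 1L)
  expect_identical(mm$coincidence_period, 442L)
  expect_true(mm$full_mismatch)
  expect_identical(symmetry_mismatch(17, 34)$gcd, 17L)
  expect_identical(symmetry_mismatch(12, 12),
                   list(gcd = 12L, coincidence_period = 12L,
                        full_mismatch = FALSE))
})

test_that("cog mesh registries count distinct rotational phases", {
  r <- mesh_registry(17, 38)
  expect_identical(r$n_distinct, 17L)
  expect_equal(length(unique(r$phases)), 17L)
  expect_identical(mesh_registry(11, 34)$n_distinct, 11L)
  expect_identical(mesh_registry(17, 34)$n_distinct, 1L)
  expect_equal(mesh_registry(17, 34)$phases, rep(0, 17))
})

test_that("mesh registry counts satisfy n_distinct * gcd = n exhaustively", {
  for (n in 1:40) {
    for (m in 1:40) {
      r <- mesh_registry(n, m)
      g <- flagmotor:::gcd_int(n, m)
      expect_identical(r$n_distinct * g, as.integer(n))
      expect_identical(length(unique(r$phases)), as.integer(r$n_distinct))
    }
  }
})
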