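#' Synthetic density phantoms for ring-shaped assemblies
#'
#' `make_ring_phantom()` builds a map containing `n_subunits` isotropic
#' Gaussian blobs evenly spaced on a circle of radius `ring_radius` about the
#' z axis, i.e. an idealized C_n ring such as the 17-fold inner basal-disk
#' ring or the 38-fold C-ring of the flagellar motor. Subunit centres sit at
#' angles `phase0 + 2*pi*j/n_subunits` (j = 0 .. n-1) at height `z_offset`.
#'
#' Blobs are truncated at 4 sigma for speed; the neglected Gaussian mass is
#' below 0.03%.
#'
#' @param n_subunits integer >= 1, the cyclic symmetry order.
#' @param ring_radius ring radius in Angstrom (> 0).
#' @param subunit_sigma isotropic Gaussian width (sd) of one subunit, A.
#' @param grid_shape integer vector of length 3 (or scalar, recycled).
#' @param voxel_size A per voxel.
#' @param z_offset axial position of the ring plane, A (default 0).
#' @param amplitude peak density of one subunit (default 1).
#' @param phase0 azimuthal phase of the first subunit, radians (default 0).
#' @return a [density_map].
#' @examples
#' ring <- make_ring_phantom(17, ring_radius = 120, subunit_sigma = 8,
#'                           grid_shape = 80, voxel_size = 4)
#' @export
make_ring_phantom <- function(n_subunits, ring_radius, subunit_sigma,
                              grid_shape, voxel_size,
                              z_offset = 0, amplitude = 1, phase0 = 0) {
  check_scalar(n_subunits, "n_subunits", positive = TRUE, integerish = TRUE)
  check_scalar(ring_radius, "ring_radius", positive = TRUE)
  check_scalar(subunit_sigma, "subunit_sigma", positive = TRUE)
  check_scalar(voxel_size, "voxel_size", positive = TRUE)
  check_scalar(z_offset, "z_offset")
  check_scalar(phase0, "phase0")
  dims <- normalize_grid_shape(grid_shape)
  half <- (dims / 2) * voxel_size
  if (ring_radius + 3 * subunit_sigma > min(half[1], half[2])) {
    stop(sprintf(
      "ring does not fit in grid: radius + 3*sigma = %.1f A exceeds half-extent %.1f A",
      ring_radius + 3 * subunit_sigma, min(half[1], half[2])), call. = FALSE)
  }
  if (abs(z_offset) + 3 * subunit_sigma > half[3]) {
    stop("ring does not fit in grid along z", call. = FALSE)
  }
  grid <- array(0, dims)
  ang <- phase0 + 2 * pi * (seq_len(n_subunits) - 1) / n_subunits
  for (j in seq_len(n_subunits)) {
    grid <- add_gaussian_blob(grid, dims, voxel_size,
                              centre = c(ring_radius * cos(ang[j]),
                                         ring_radius * sin(ang[j]),
                                         z_offset),
                              sigma = subunit_sigma, amplitude = amplitude)
  }
  density_map(grid, voxel_size)
}

#' Concentric-ring basal-disk phantom
#'
#' Builds one Gaussian blob per protomer for every ring of a
#' [disk_lattice_model]: ring i sits at radius `R1 * (1 + spacing_ratio *
#' (i - 1))` and carries the protomer count given by
#' [ring_protomer_counts()]. Only the innermost ring need share the global
#' cyclic symmetry; outer rings have their own counts, reproducing the
#' symmetry mismatch of a multi-ring disk.
#'
#' @param model a [disk_lattice_model].
#' @param subunit_sigma Gaussian width of one protomer, A.
#' @param grid_shape,voxel_size as in [make_ring_phantom()].
#' @param z_offset,amplitude,phase0 as in [make_ring_phantom()]; `phase0`
#'   applies to every ring.
#' @return a [density_map].
#' @export
make_concentric_disk_phantom <- function(model, subunit_sigma, grid_shape,
                                         voxel_size, z_offset = 0,
                                         amplitude = 1, phase0 = 0) {
  if (!inherits(model, "disk_lattice_model")) {
    stop("'model' must be a disk_lattice_model", call. = FALSE)
  }
  counts <- ring_protomer_counts(model)
  radii <- ring_radii(model)
  dims <- normalize_grid_shape(grid_shape)
  half <- (dims / 2) * voxel_size
  if (max(radii) + 3 * subunit_sigma > min(half[1], half[2])) {
    stop(sprintf(
      "disk does not fit in grid: outer radius + 3*sigma = %.1f A exceeds half-extent %.1f A",
      max(radii) + 3 * subunit_sigma, min(half[1], half[2])), call. = FALSE)
  }
  grid <- array(0, dims)
  out <- density_map(grid, voxel_size)
  for (i in seq_along(radii)) {
    ring <- make_ring_phantom(counts[i], radii[i], subunit_sigma,
                              dims, voxel_size, z_offset = z_offset,
                              amplitude = amplitude, phase0 = phase0)
    out$grid <- out$grid + ring$grid
  }
  attr(out, "ring_radii") <- radii
  attr(out, "ring_counts") <- counts
  out
}

#' Cylindrical-shell phantom
#'
#' An azimuthally uniform Gaussian shell in radius about the z axis, boxcar
#' in z: a model of lathed cylindrical features such as the FliF beta-collar
#' of the MS-ring. Density is
#' `amplitude * exp(-(r - radius)^2 / (2 wall_sigma^2))` for `|z| <=
#' height/2` and 0 outside.
#'
#' @param radius shell radius, A.
#' @param height axial extent of the shell, A.
#' @param wall_sigma radial Gaussian width of the wall, A.
#' @param grid_shape,voxel_size as in [make_ring_phantom()].
#' @param amplitude peak density (default 1).
#' @return a [density_map].
#' @export
make_cylinder_phantom <- function(radius, height, wall_sigma, grid_shape,
                                  voxel_size, amplitude = 1) {
  check_scalar(radius, "radius", positive = TRUE)
  check_scalar(height, "height", positive = TRUE)
  check_scalar(wall_sigma, "wall_sigma", positive = TRUE)
  check_scalar(voxel_size, "voxel_size", positive = TRUE)
  dims <- normalize_grid_shape(grid_shape)
  half <- (dims / 2) * voxel_size
  if (radius + 3 * wall_sigma > min(half[1], half[2])) {
    stop(sprintf(
      "cylinder does not fit in grid: radius + 3*sigma = %.1f A exceeds half-extent %.1f A",
      radius + 3 * wall_sigma, min(half[1], half[2])), call. = FALSE)
  }
  xs <- axis_coords(dims[1], voxel_size)
  ys <- axis_coords(dims[2], voxel_size)
  zs <- axis_coords(dims[3], voxel_size)
  r2d <- sqrt(outer(xs^2, ys^2, `+`))
  slice <- amplitude * exp(-(r2d - radius)^2 / (2 * wall_sigma^2))
  inz <- abs(zs) <= height / 2
  grid <- array(0, dims)
  for (k in which(inz)) grid[, , k] <- slice
  density_map(grid, voxel_size)
}

#' Independent-noise half maps from a signal map
#'
#' Adds two independent white Gaussian noise realizations to a signal map,
#' scaled so that the ratio of voxel variances signal/noise equals `snr`,
#' mimicking the two half-set reconstructions used for gold-standard FSC
#' resolution estimation. A fixed `seed` gives bit-identical output on
#' repeat; the caller's RNG state is untouched.
#'
#' @param map a [density_map] holding the common signal.
#' @param snr signal-to-noise variance ratio (> 0; `Inf` gives noise-free
#'   copies).
#' @param seed integer seed for the noise.
#' @return list with elements `half1` and `half2`, both [density_map]s.
#' @export
make_half_maps <- function(map, snr, seed = 1L) {
  stop_if_not_map(map)
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0) {
    stop("'snr' must be a single value > 0", call. = FALSE)
  }
  sig_var <- stats::var(as.vector(map$grid))
  noise_sd <- if (is.infinite(snr)) 0 else sqrt(sig_var / snr)
  d <- dim(map$grid)
  with_seed(seed, {
    n1 <- array(stats::rnorm(prod(d), sd = noise_sd), d)
    n2 <- array(stats::rnorm(prod(d), sd = noise_sd), d)
    list(half1 = density_map(map$grid + n1, map$voxel_size),
         half2 = density_map(map$grid + n2, map$voxel_size))
  })
}

# --- internals -------------------------------------------------------------

normalize_grid_shape <- function(grid_shape) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  if (length(grid_shape) != 3L || any(grid_shape < 8) ||
      any(grid_shape != round(grid_shape))) {
    stop("'grid_shape' must be 1 or 3 integers, each >= 8", call. = FALSE)
  }
  as.integer(grid_shape)
}

# Add one isotropic Gaussian blob (separable, truncated at 4 sigma).
add_gaussian_blob <- function(grid, dims, voxel_size, centre, sigma,
                              amplitude, trunc = 4) {
  xs <- axis_coords(dims[1], voxel_size)
  ys <- axis_coords(dims[2], voxel_size)
  zs <- axis_coords(dims[3], voxel_size)
  ix <- which(abs(xs - centre[1]) <= trunc * sigma)
  iy <- which(abs(ys - centre[2]) <= trunc * sigma)
  iz <- which(abs(zs - centre[3]) <= trunc * sigma)
  if (!length(ix) || !length(iy) || !length(iz)) return(grid)
  gx <- exp(-(xs[ix] - centre[1])^2 / (2 * sigma^2))
  gy <- exp(-(ys[iy] - centre[2])^2 / (2 * sigma^2))
  gz <- exp(-(zs[iz] - centre[3])^2 / (2 * sigma^2))
  blob <- amplitude * outer(outer(gx, gy), gz)
  grid[ix, iy, iz] <- grid[ix, iy, iz] + blob
  grid
}
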