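#' 3D density map with physical voxel size
#'
#' The basic container for voxelized scalar density, as used for cryo-EM
#' reconstructions of ring-shaped assemblies. The grid is a 3D numeric array
#' with isotropic voxel size in Angstrom. By convention the cyclic-symmetry
#' axis is +z and passes through the geometric centre of the grid; angles are
#' measured counter-clockwise viewed from +z in a right-handed frame.
#'
#' @param grid 3D numeric array of densities (arbitrary units), all finite.
#' @param voxel_size voxel edge length in Angstrom (> 0, isotropic).
#' @return an object of class `density_map` with fields `grid` and
#'   `voxel_size`.
#' @examples
#' m <- density_map(array(0, c(8, 8, 8)), voxel_size = 2)
#' dim(m$grid)
#' @export
density_map <- function(grid, voxel_size) {
  if (!is.array(grid) || length(dim(grid)) != 3L || !is.numeric(grid)) {
    stop("'grid' must be a 3D numeric array", call. = FALSE)
  }
  if (any(dim(grid) < 8L)) {
    stop("grid dimensions must be at least 8 in each axis", call. = FALSE)
  }
  check_scalar(voxel_size, "voxel_size", positive = TRUE)
  if (!all(is.finite(grid))) {
    stop("all density values must be finite", call. = FALSE)
  }
  storage.mode(grid) <- "double"
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_map> %d x %d x %d voxels @ %.4g A/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  density range [%.4g, %.4g], total %.4g\n",
              min(x$grid), max(x$grid), sum(x$grid)))
  invisible(x)
}

is_density_map <- function(x) inherits(x, "density_map")

stop_if_not_map <- function(x, name = "map") {
  if (!is_density_map(x)) {
    stop(sprintf("'%s' must be a density_map", name), call. = FALSE)
  }
  invisible(x)
}

# Coordinates of voxel centres along each axis, Angstrom, origin at centre.
map_coords <- function(map) {
  d <- dim(map$grid)
  list(x = axis_coords(d[1], map$voxel_size),
       y = axis_coords(d[2], map$voxel_size),
       z = axis_coords(d[3], map$voxel_size))
}

# Half-extent (distance from grid centre to the nearest face) per axis, A.
map_half_extent <- function(map_or_dims, voxel_size = NULL) {
  if (is_density_map(map_or_dims)) {
    d <- dim(map_or_dims$grid)
    vs <- map_or_dims$voxel_size
  } else {
    d <- map_or_dims
    vs <- voxel_size
  }
  (d / 2) * vs
}

#' Interpolate a density map at arbitrary physical coordinates
#'
#' Trilinear interpolation of the voxel grid at physical (x, y, z) positions
#' in Angstrom (origin at the grid centre). Positions outside the grid
#' evaluate to 0.
#'
#' @param map a [density_map].
#' @param x,y,z numeric vectors of equal length, Angstrom.
#' @return numeric vector of interpolated densities.
#' @keywords internal
map_interpolate <- function(map, x, y, z) {
  d <- dim(map$grid)
  vs <- map$voxel_size
  fx <- x / vs + (d[1] + 1) / 2
  fy <- y / vs + (d[2] + 1) / 2
  fz <- z / vs + (d[3] + 1) / 2
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  out <- numeric(length(x))
  ok <- i0 >= 1 & i0 + 1 <= d[1] &
        j0 >= 1 & j0 + 1 <= d[2] &
        k0 >= 1 & k0 + 1 <= d[3]
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  wx <- wx[ok]; wy <- wy[ok]; wz <- wz[ok]
  g <- map$grid
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- (k0 - 1) * n12 + (j0 - 1) * n1 + i0
  v <- (1 - wx) * (1 - wy) * (1 - wz) * g[base] +
       wx       * (1 - wy) * (1 - wz) * g[base + 1] +
       (1 - wx) * wy       * (1 - wz) * g[base + n1] +
       wx       * wy       * (1 - wz) * g[base + n1 + 1] +
       (1 - wx) * (1 - wy) * wz       * g[base + n12] +
       wx       * (1 - wy) * wz       * g[base + n12 + 1] +
       (1 - wx) * wy       * wz       * g[base + n12 + n1] +
       wx       * wy       * wz       * g[base + n12 + n1 + 1]
  out[ok] <- v
  out
}

#' Total integrated density of a map
#'
#' Sum of voxel values times voxel volume, in density units times cubic
#' Angstrom.
#'
#' @param map a [density_map].
#' @return scalar integral.
#' @export
map_total_density <- function(map) {
  stop_if_not_map(map)
  sum(map$grid) * map$voxel_size^3
}
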