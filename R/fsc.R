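#' Fourier shell correlation between two maps
#'
#' Per-shell normalized cross-correlation of the Fourier transforms of two
#' maps sharing shape and voxel size, the standard resolution statistic for
#' half-set reconstructions. Shells are one reciprocal voxel wide; cubic
#' grids are required so that shells are isotropic in 1/A. No masking or
#' phase-randomization correction is applied.
#'
#' @param map_a,map_b [density_map]s of identical cubic shape and voxel
#'   size.
#' @return object of class `fsc_curve`: list with `spatial_frequency`
#'   (shell centres, 1/A, from DC to Nyquist), `correlation`, and the
#'   conventional `thresholds` (0.143 half-map, 0.5 map-model).
#' @export
fsc_curve <- function(map_a, map_b) {
  stop_if_not_map(map_a, "map_a")
  stop_if_not_map(map_b, "map_b")
  da <- dim(map_a$grid); db <- dim(map_b$grid)
  if (!identical(da, db)) stop("maps must share grid shape", call. = FALSE)
  if (abs(map_a$voxel_size - map_b$voxel_size) > 1e-9) {
    stop("maps must share voxel size", call. = FALSE)
  }
  if (length(unique(da)) != 1L) {
    stop("FSC requires cubic grids", call. = FALSE)
  }
  n <- da[1]
  vs <- map_a$voxel_size
  Fa <- stats::fft(map_a$grid)
  Fb <- stats::fft(map_b$grid)
  # frequency index per axis in cycles/box, wrapped
  fi <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) # length n
  fr <- sqrt(outer(outer(fi^2, fi^2, `+`), fi^2, `+`))
  shell <- as.integer(round(as.vector(fr))) + 1L
  nshell <- n %/% 2 + 1L
  keep <- shell <= nshell
  shell <- factor(shell[keep], levels = seq_len(nshell))
  num <- as.vector(tapply(Re(as.vector(Fa * Conj(Fb)))[keep], shell, sum,
                          default = 0))
  pa <- as.vector(tapply(as.vector(Mod(Fa)^2)[keep], shell, sum, default = 0))
  pb <- as.vector(tapply(as.vector(Mod(Fb)^2)[keep], shell, sum, default = 0))
  denom <- sqrt(pa * pb)
  corr <- ifelse(denom > 0, num / denom, 0)
  structure(list(spatial_frequency = (seq_len(nshell) - 1) / (n * vs),
                 correlation = corr,
                 thresholds = c(half_map = 0.143, map_model = 0.5)),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells to %.4g 1/A\n",
              length(x$correlation), max(x$spatial_frequency)))
  invisible(x)
}

#' Resolution at an FSC threshold
#'
#' The reciprocal of the spatial frequency at which the FSC curve first
#' crosses below `threshold`, linearly interpolated between shells. If the
#' curve never crosses, the Nyquist resolution bound is returned with
#' attribute `crossed = FALSE` (the map is at least that well resolved).
#'
#' @param curve an [fsc_curve].
#' @param threshold FSC threshold (0.143 for half maps, 0.5 for map-model).
#' @return resolution in Angstrom, with logical attribute `crossed`.
#' @export
resolution_at_threshold <- function(curve, threshold = 0.143) {
  if (!inherits(curve, "fsc_curve")) {
    stop("'curve' must be an fsc_curve", call. = FALSE)
  }
  check_scalar(threshold, "threshold")
  f <- curve$spatial_frequency
  c_ <- curve$correlation
  below <- which(c_ < threshold)
  below <- below[below > 1L]  # ignore DC
  if (!length(below)) {
    return(structure(1 / max(f), crossed = FALSE))
  }
  i <- below[1]
  f_cross <- f[i - 1] + (c_[i - 1] - threshold) / (c_[i - 1] - c_[i]) *
    (f[i] - f[i - 1])
  structure(1 / f_cross, crossed = TRUE)
}

#' Low-pass filter a map at a resolution cutoff
#'
#' Sharp spherical cutoff in Fourier space at `cutoff` Angstrom, used to
#' build maps of known band limit for validating FSC resolution estimation.
#'
#' @param map a [density_map] (cubic grid).
#' @param cutoff resolution cutoff, A.
#' @return a [density_map].
#' @export
lowpass_map <- function(map, cutoff) {
  stop_if_not_map(map)
  check_scalar(cutoff, "cutoff", positive = TRUE)
  d <- dim(map$grid)
  if (length(unique(d)) != 1L) stop("cubic grid required", call. = FALSE)
  n <- d[1]
  vs <- map$voxel_size
  fi <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * vs)
  fr <- sqrt(outer(outer(fi^2, fi^2, `+`), fi^2, `+`))
  mask <- fr <= 1 / cutoff
  filt <- Re(stats::fft(stats::fft(map$grid) * mask, inverse = TRUE)) / n^3
  density_map(filt, vs)
}
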