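# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so package functions never perturb the global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Physical coordinates (Angstrom) of voxel centres along one axis: the grid
# origin sits at the geometric centre of the voxel grid.
axis_coords <- function(n, voxel_size) {
  (seq_len(n) - (n + 1) / 2) * voxel_size
}

wrap_angle <- function(theta) {
  theta %% (2 * pi)
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  }
  invisible(x)
}

#' Convert between map (Angstrom) and bead-assay (nanometre) length units
#'
#' Density maps carry lengths in Angstrom while bead trajectories and the
#' stator torque model work in nanometres. Conversions are only ever done
#' through these named helpers (1 nm = 10 Angstrom) so that no silent unit
#' mixing can occur.
#'
#' @param x numeric vector of lengths.
#' @return numeric vector in the target unit.
#' @export
angstrom_to_nm <- function(x) x / 10

#' @rdname angstrom_to_nm
#' @export
nm_to_angstrom <- function(x) x * 10
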