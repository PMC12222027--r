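#' Concentric-ring lattice model of the basal disk
#'
#' Geometric stoichiometry model for a disk built from concentric protein
#' rings, as for the FlgP basal disk: the innermost ring has `n1` protomers
#' at radius `R1`, successive rings are spaced by a constant radial increment
#' `spacing_ratio * R1`, and the arc length per protomer, `s = 2*pi*R1/n1`,
#' is assumed constant across rings so that each ring's protomer count
#' follows from the ratio of its circumference to the inner one.
#'
#' For the packaged default geometry (`n1 = 51`, `spacing_ratio = 0.216`)
#' each subsequent ring adds 11 protomers, which is what creates the symmetry
#' mismatch between the 17-fold inner ring and the outer rings.
#'
#' @param R1 inner ring radius, Angstrom (> 0). The stoichiometry depends
#'   only on ratios, so any positive value works when absolute radii are not
#'   needed.
#' @param n1 inner ring protomer count (integer >= 1).
#' @param spacing_ratio radial ring spacing divided by `R1` (> 0).
#' @param n_rings number of rings (integer >= 1).
#' @return an object of class `disk_lattice_model`.
#' @examples
#' m <- disk_lattice_model(R1 = 180, n1 = 51, spacing_ratio = 0.216,
#'                         n_rings = 5)
#' ring_protomer_counts(m)  # 51 62 73 84 95
#' protomer_increment(m)    # 11
#' @export
disk_lattice_model <- function(R1 = 180, n1 = 51L, spacing_ratio = 0.216,
                               n_rings = 5L) {
  check_scalar(R1, "R1", positive = TRUE)
  check_scalar(n1, "n1", positive = TRUE, integerish = TRUE)
  check_scalar(spacing_ratio, "spacing_ratio", positive = TRUE)
  check_scalar(n_rings, "n_rings", positive = TRUE, integerish = TRUE)
  structure(list(R1 = as.numeric(R1), n1 = as.integer(n1),
                 spacing_ratio = as.numeric(spacing_ratio),
                 n_rings = as.integer(n_rings)),
            class = "disk_lattice_model")
}

#' @export
print.disk_lattice_model <- function(x, ...) {
  cat(sprintf(
    "<disk_lattice_model> R1 = %.4g A, n1 = %d, spacing_ratio = %.4g, %d rings\n",
    x$R1, x$n1, x$spacing_ratio, x$n_rings))
  cat("  counts:", paste(ring_protomer_counts(x), collapse = " "), "\n")
  invisible(x)
}

#' Arc length per protomer on a ring
#'
#' The circumference of a ring of radius `R1` divided by its protomer count:
#' `2*pi*R1 / n1`, in the units of `R1`.
#'
#' @param R1 ring radius (> 0).
#' @param n1 protomer count (integer >= 1).
#' @return arc spacing, same units as `R1`.
#' @export
arc_spacing <- function(R1, n1) {
  check_scalar(R1, "R1", positive = TRUE)
  check_scalar(n1, "n1", positive = TRUE, integerish = TRUE)
  2 * pi * R1 / n1
}

#' Ring radii of a disk lattice model
#'
#' Radius of ring i is `R1 * (1 + spacing_ratio * (i - 1))`.
#'
#' @param model a [disk_lattice_model].
#' @return numeric vector of radii, Angstrom.
#' @export
ring_radii <- function(model) {
  stopifnot(inherits(model, "disk_lattice_model"))
  model$R1 * (1 + model$spacing_ratio * (seq_len(model$n_rings) - 1))
}

#' Protomer counts of the concentric rings
#'
#' Under the constant-arc-spacing assumption the count of ring i is the
#' nearest integer to `n1 * R_i / R1` (circumference ratio), with
#' round-half-to-even tie breaking.
#'
#' @param model a [disk_lattice_model].
#' @return integer vector of per-ring protomer counts.
#' @export
ring_protomer_counts <- function(model) {
  stopifnot(inherits(model, "disk_lattice_model"))
  as.integer(round(model$n1 * ring_radii(model) / model$R1))
}

#' Protomer increment between successive rings
#'
#' The per-gap differences of [ring_protomer_counts()]. When the increments
#' are all equal the common value is returned as a scalar with names
#' dropped; otherwise the full vector of per-gap increments is returned.
#'
#' @param model a [disk_lattice_model] with at least 2 rings.
#' @return integer scalar (constant increment) or vector of increments.
#' @export
protomer_increment <- function(model) {
  counts <- ring_protomer_counts(model)
  if (length(counts) < 2L) {
    stop("need at least 2 rings to compute an increment", call. = FALSE)
  }
  inc <- diff(counts)
  if (length(unique(inc)) == 1L) inc[1] else inc
}

#' Total protomers from cyclic symmetry and asymmetric-unit content
#'
#' The protomer total of a C_n ring is the symmetry order times the number
#' of protomers per asymmetric unit, e.g. 17 trimeric repeats give a ring of
#' 51 subunits.
#'
#' @param symmetry_order cyclic symmetry order (integer >= 1).
#' @param protomers_per_asu protomers per asymmetric unit (integer >= 1).
#' @return integer product.
#' @examples
#' asu_total(17, 3)  # 51
#' @export
asu_total <- function(symmetry_order, protomers_per_asu) {
  check_scalar(symmetry_order, "symmetry_order", positive = TRUE,
               integerish = TRUE)
  check_scalar(protomers_per_asu, "protomers_per_asu", positive = TRUE,
               integerish = TRUE)
  as.integer(round(symmetry_order) * round(protomers_per_asu))
}

#' Symmetry mismatch between two cyclic symmetries
#'
#' Greatest common divisor and coincidence period (least common multiple) of
#' two symmetry orders. `gcd = 1` is a full mismatch: no two subunits of the
#' two rings can be in equivalent register, as for the 17-fold basal disk
#' against the 26-fold LP-rings.
#'
#' @param a,b cyclic symmetry orders (integers >= 1).
#' @return list with `gcd`, `coincidence_period` (lcm) and logical
#'   `full_mismatch` (`gcd == 1`).
#' @examples
#' symmetry_mismatch(17, 26)  # gcd 1: full mismatch
#' @export
symmetry_mismatch <- function(a, b) {
  check_scalar(a, "a", positive = TRUE, integerish = TRUE)
  check_scalar(b, "b", positive = TRUE, integerish = TRUE)
  g <- gcd_int(round(a), round(b))
  list(gcd = as.integer(g),
       coincidence_period = as.integer(round(a) * round(b) / g),
       full_mismatch = g == 1L)
}

#' Rotational mesh registry of small cogs around a large cogwheel
#'
#' For `n_small` cogs evenly distributed around a large cog with `m_teeth`
#' teeth (the stator pentamers around the C-ring in the cogwheel model of
#' flagellar rotation), cog k faces tooth phase `frac(m_teeth * k /
#' n_small)`. If `gcd(n_small, m_teeth) = 1` every cog must adopt a
#' different rotational register to mesh simultaneously; a fully
#' commensurate pair meshes identically.
#'
#' @param n_small number of small cogs (integer >= 1).
#' @param m_teeth teeth on the big cog (integer >= 1).
#' @return list with `phases` (fractional tooth phases in `[0, 1)`, one per
#'   small cog) and `n_distinct` (`n_small / gcd(n_small, m_teeth)`).
#' @examples
#' mesh_registry(17, 38)$n_distinct  # 17: all registries different
#' mesh_registry(17, 34)$n_distinct  # 1: all cogs mesh identically
#' @export
mesh_registry <- function(n_small, m_teeth) {
  check_scalar(n_small, "n_small", positive = TRUE, integerish = TRUE)
  check_scalar(m_teeth, "m_teeth", positive = TRUE, integerish = TRUE)
  n <- as.integer(round(n_small)); m <- as.integer(round(m_teeth))
  k <- 0:(n - 1)
  phases <- (m * k) %% n / n
  list(phases = phases,
       n_distinct = as.integer(n / gcd_int(n, m)))
}

gcd_int <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b != 0) {
    t <- b
    b <- a %% b
    a <- t
  }
  a
}
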