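#' Stator ring for the additive torque model
#'
#' Holds the three quantities that set the maximum torque of a flagellar
#' motor in the additive stator model: the number of engaged stator
#' complexes `N`, the tangential force each exerts on the C-ring `F` (pN),
#' and the radius of the stator-to-C-ring contact `r` (nm). Units are
#' enforced at construction: forces in piconewtons, radii in nanometres
#' (convert map radii from Angstrom with [angstrom_to_nm()]).
#'
#' @param N stator complex count (>= 0).
#' @param F_pN per-stator tangential force, pN (>= 0).
#' @param r_nm contact radius, nm (>= 0).
#' @return an object of class `stator_ring`.
#' @examples
#' cj <- stator_ring(N = 17, F_pN = 7.3, r_nm = 26.5)
#' predict_torque(cj)$torque  # 3288.65 pN nm
#' @export
stator_ring <- function(N, F_pN, r_nm) {
  check_scalar(N, "N", nonneg = TRUE)
  check_scalar(F_pN, "F_pN", nonneg = TRUE)
  check_scalar(r_nm, "r_nm", nonneg = TRUE)
  structure(list(N = as.numeric(N), F_pN = as.numeric(F_pN),
                 r_nm = as.numeric(r_nm)),
            class = "stator_ring")
}

#' @export
print.stator_ring <- function(x, ...) {
  cat(sprintf("<stator_ring> N = %g, F = %g pN, r = %g nm\n",
              x$N, x$F_pN, x$r_nm))
  invisible(x)
}

#' Predict maximum motor torque from an additive stator model
#'
#' Treating the torque contributions of the stator complexes as additive,
#' the maximum torque is simply `N * F * r` (pN nm): stator count times
#' per-stator tangential force times contact radius. With the packaged
#' constants this predicts 3,288.65 pN nm for the 17-stator C. jejuni motor
#' and 1,606 pN nm for the 11-stator E. coli/Salmonella motor.
#'
#' @param ring a [stator_ring].
#' @return list of class `torque_prediction` with `torque` (pN nm) and
#'   `provenance` (echo of the inputs).
#' @export
predict_torque <- function(ring) {
  if (!inherits(ring, "stator_ring")) {
    stop("'ring' must be a stator_ring", call. = FALSE)
  }
  structure(list(torque = ring$N * ring$F_pN * ring$r_nm,
                 provenance = unclass(ring)),
            class = "torque_prediction")
}

#' @export
print.torque_prediction <- function(x, ...) {
  cat(sprintf("<torque_prediction> %.4f pN nm (N = %g, F = %g pN, r = %g nm)\n",
              x$torque, x$provenance$N, x$provenance$F_pN, x$provenance$r_nm))
  invisible(x)
}

#' Infer per-stator force from a measured torque
#'
#' Exact inverse of [predict_torque()]: `F = torque / (N * r)`. Given the
#' observed ~1,606 pN nm torque of an 11-stator motor at a 20 nm contact
#' radius this recovers the 7.3 pN per-stator force estimate.
#'
#' @param torque_pNnm motor torque, pN nm.
#' @param N stator count (> 0).
#' @param r_nm contact radius, nm (> 0).
#' @return per-stator force, pN.
#' @examples
#' infer_stator_force(1606, N = 11, r_nm = 20)  # 7.3
#' @export
infer_stator_force <- function(torque_pNnm, N, r_nm) {
  check_scalar(torque_pNnm, "torque_pNnm", nonneg = TRUE)
  check_scalar(N, "N", positive = TRUE)
  check_scalar(r_nm, "r_nm", positive = TRUE)
  torque_pNnm / (N * r_nm)
}

#' Compare the predicted torque of two motors
#'
#' Reports the torque ratio of two stator rings and its exact decomposition
#' into stator-count, force and radius ratios (their product equals the
#' torque ratio by construction).
#'
#' @param ring_a,ring_b [stator_ring]s; the ratio is a over b.
#' @return list with `torque_a`, `torque_b`, `ratio`, and `decomposition`
#'   (named vector of N, F and r ratios).
#' @examples
#' compare_motors(stator_ring(17, 7.3, 26.5), stator_ring(11, 7.3, 20))
#' @export
compare_motors <- function(ring_a, ring_b) {
  ta <- predict_torque(ring_a)$torque
  tb <- predict_torque(ring_b)$torque
  if (ta <= 0 || tb <= 0) {
    stop("both torques must be > 0 for a ratio comparison", call. = FALSE)
  }
  list(torque_a = ta, torque_b = tb, ratio = ta / tb,
       decomposition = c(N_ratio = ring_a$N / ring_b$N,
                         F_ratio = ring_a$F_pN / ring_b$F_pN,
                         r_ratio = ring_a$r_nm / ring_b$r_nm))
}

#' Packaged motor constants
#'
#' Named constants used throughout the package for the C. jejuni and
#' E. coli/Salmonella flagellar motors. Counts and forces are literature
#' values; the two stator contact radii are structural constants derived
#' from the additive torque model and the published torque predictions
#' (3,288 = 17 * 7.3 * r and 1,606 = 11 * 7.3 * r), since contact radii are
#' not printed directly. Override them with measurements from deposited
#' maps where available.
#'
#' @return named list: `N_cj` (17 stators), `N_ec` (11), `F_stator_pN`
#'   (7.3), `r_cj_nm` (26.5, derived), `r_ec_nm` (20.0, derived),
#'   `disk_n1` (51 inner-ring protomers), `disk_asu` (17),
#'   `disk_protomers_per_asu` (3), `disk_spacing_ratio` (0.216, derived),
#'   `lp_ring_steps` (26), `cring_teeth_cj` (38), `cring_teeth_ec` (34).
#' @export
motor_constants <- function() {
  list(
    N_cj = 17L,                 # stator complexes, C. jejuni
    N_ec = 11L,                 # stator complexes, E. coli / Salmonella
    F_stator_pN = 7.3,          # per-stator tangential force
    r_cj_nm = 26.5,             # derived contact radius, C. jejuni
    r_ec_nm = 20.0,             # derived contact radius, E. coli/Salmonella
    disk_n1 = 51L,              # inner basal-disk ring protomers
    disk_asu = 17L,             # inner-ring cyclic symmetry
    disk_protomers_per_asu = 3L,
    disk_spacing_ratio = 0.216, # derived so successive rings add 11
    lp_ring_steps = 26L,        # LP-ring periodicity (dwells per rev)
    cring_teeth_cj = 38L,       # C-ring periodicity, C. jejuni
    cring_teeth_ec = 34L        # C-ring periodicity, E. coli/Salmonella
  )
}
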