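# Intra-polymer interaction model: FENE bonds, repulsive Lennard-Jones
# (excluded volume), bending rigidity, optional Debye-Hueckel electrostatics.
# The scalar functions below are the model's closed forms; the per-step force
# assembly runs in compiled code (total_forces()).

#' Interaction parameters of the bead-spring chain
#'
#' Kremer-Grest defaults: FENE with k = 30 epsilon/sigma^2, R0 = 1.5 sigma,
#' combined with the repulsive (WCA) Lennard-Jones core on all pairs
#' (bonded pairs included), giving an equilibrium bond length of about
#' 0.97 sigma. The bending constant `bend_kappa` is calibrated so the free
#' chain's persistence length is about 10 sigma (see
#' [calibrate_bending_rigidity()]). Electrostatics are a screened Coulomb
#' (Debye-Hueckel) repulsion `U = T* A exp(-r/lambda_D)/r` acting between
#' nonbonded pairs when `charged = TRUE`; the energy scales linearly with
#' reduced temperature, so electrostatic forces grow with T* and shrink as
#' the system is cooled.
#'
#' @param fene_k,fene_r0 FENE spring strength (epsilon/sigma^2) and maximum
#'   extension (sigma).
#' @param lj_epsilon,lj_sigma,lj_cutoff excluded-volume energy scale, bead
#'   diameter and cutoff (default 2^(1/6) sigma: purely repulsive).
#' @param bend_kappa bending constant, epsilon per interior joint.
#' @param charged logical; enable backbone electrostatics?
#' @param charge_prefactor reduced prefactor A (effective Bjerrum length
#'   times squared charge per bead), length units.
#' @param debye_length Debye screening length, sigma (0.75 sigma = 1.9 nm).
#' @param elec_cutoff electrostatic truncation radius, sigma.
#' @return An object of class `interaction_params`.
#' @export
interaction_params <- function(fene_k = 30, fene_r0 = 1.5, lj_epsilon = 1,
                               lj_sigma = 1, lj_cutoff = 2^(1 / 6),
                               bend_kappa = config_defaults()$interaction$bend_kappa,
                               charged = FALSE,
                               charge_prefactor = config_defaults()$interaction$charge_prefactor,
                               debye_length = 0.75, elec_cutoff = 3) {
  stopifnot(fene_k >= 0, fene_r0 > 1, lj_epsilon >= 0, lj_sigma > 0,
            lj_cutoff > 0, bend_kappa >= 0, charge_prefactor >= 0,
            debye_length > 0)
  if (elec_cutoff <= debye_length)
    .pp_error("phagepack_invalid_value", "elec_cutoff must exceed debye_length")
  structure(
    list(fene_k = fene_k, fene_r0 = fene_r0, lj_epsilon = lj_epsilon,
         lj_sigma = lj_sigma, lj_cutoff = lj_cutoff, bend_kappa = bend_kappa,
         charged = isTRUE(charged), charge_prefactor = charge_prefactor,
         debye_length = debye_length, elec_cutoff = elec_cutoff),
    class = "interaction_params"
  )
}

params_from_config <- function(config) {
  i <- config$interaction
  interaction_params(
    fene_k = i$fene_k, fene_r0 = i$fene_r0, lj_epsilon = i$lj_epsilon,
    lj_sigma = i$lj_sigma, lj_cutoff = i$lj_cutoff,
    bend_kappa = i$bend_kappa, charged = config$charged,
    charge_prefactor = i$charge_prefactor, debye_length = i$debye_length,
    elec_cutoff = i$elec_cutoff
  )
}

#' FENE bond energy and force
#'
#' `U(r) = -k R0^2/2 * log(1 - (r/R0)^2)`, finite for r < R0 and divergent at
#' the maximum extension R0, which prevents bond breaking and chain crossing.
#'
#' @param r scalar (or vector) bead separation, sigma; must satisfy
#'   `0 <= r < fene_r0`.
#' @param params an [interaction_params()].
#' @return List with `energy` and `force` (the scalar restoring force
#'   magnitude `-dU/dr`; negative values pull the beads together).
#' @export
fene_bond <- function(r, params = interaction_params()) {
  if (any(r < 0) || any(r >= params$fene_r0))
    .pp_error("phagepack_overstretched_bond",
              "FENE bond separation must lie in [0, R0 = %g)", params$fene_r0)
  k <- params$fene_k
  r0 <- params$fene_r0
  denom <- 1 - (r / r0)^2
  list(energy = -0.5 * k * r0^2 * log(denom), force = -k * r / denom)
}

#' Excluded-volume (truncated-shifted Lennard-Jones) energy and force
#'
#' `U(r) = 4 eps [(sigma/r)^12 - (sigma/r)^6] - U_LJ(r_c)` for `r < r_c`, zero
#' beyond. With the default cutoff `2^(1/6) sigma` this is the purely
#' repulsive WCA core (good-solvent behavior): energy and force both vanish
#' continuously at the cutoff.
#'
#' @param r scalar (or vector) separation, sigma; must be positive.
#' @inheritParams fene_bond
#' @return List with `energy` and scalar `force` (`-dU/dr`; positive values
#'   push the beads apart).
#' @export
excluded_volume <- function(r, params = interaction_params()) {
  if (any(r <= 0))
    .pp_error("phagepack_singularity", "excluded_volume requires r > 0")
  eps <- params$lj_epsilon
  sig <- params$lj_sigma
  rc <- params$lj_cutoff
  shift <- -4 * eps * ((sig / rc)^12 - (sig / rc)^6)
  sr6 <- (sig / r)^6
  energy <- ifelse(r < rc, 4 * eps * (sr6^2 - sr6) + shift, 0)
  force <- ifelse(r < rc, 24 * eps * (2 * sr6^2 - sr6) / r, 0)
  list(energy = energy, force = force)
}

#' Bending energy and forces for a bead triplet
#'
#' `U = kappa (1 - cos theta)` where theta is the angle between the two bond
#' vectors of three consecutive beads. Forces are the exact negative
#' gradient; they sum to zero (no net translation or torque).
#'
#' @param triplet a 3 x 3 matrix, one bead position per row.
#' @inheritParams fene_bond
#' @return List with `energy` and `forces` (3 x 3 matrix, one force per
#'   bead).
#' @export
bending <- function(triplet, params = interaction_params()) {
  stopifnot(is.matrix(triplet), nrow(triplet) == 3, ncol(triplet) == 3)
  b1 <- triplet[2, ] - triplet[1, ]
  b2 <- triplet[3, ] - triplet[2, ]
  n1 <- sqrt(sum(b1^2))
  n2 <- sqrt(sum(b2^2))
  if (n1 < 1e-12 || n2 < 1e-12)
    .pp_error("phagepack_degenerate_geometry", "zero-length bond in triplet")
  kappa <- params$bend_kappa
  ct <- sum(b1 * b2) / (n1 * n2)
  g1 <- b2 / (n1 * n2) - ct * b1 / n1^2   # dcos/db1
  g2 <- b1 / (n1 * n2) - ct * b2 / n2^2   # dcos/db2
  f1 <- -kappa * g1
  f3 <- kappa * g2
  list(energy = kappa * (1 - ct), forces = rbind(f1, -(f1 + f3), f3,
                                                 deparse.level = 0))
}

#' Screened (Debye-Hueckel) electrostatic energy and force
#'
#' `U(r) = T* A exp(-r / lambda_D) / r` for `r < elec_cutoff`, zero beyond.
#' Both energy and force scale linearly with the reduced temperature, so the
#' electrostatic repulsion strengthens on heating and weakens on cooling.
#'
#' @param r scalar (or vector) separation, sigma; must be positive.
#' @param reduced_temperature T*.
#' @inheritParams fene_bond
#' @return List with `energy` and scalar `force` (`-dU/dr`, repulsive).
#' @export
electrostatic <- function(r, reduced_temperature = 1,
                          params = interaction_params(charged = TRUE)) {
  if (!params$charged)
    .pp_error("phagepack_invalid_value", "electrostatics require charged = TRUE")
  if (any(r <= 0))
    .pp_error("phagepack_singularity", "electrostatic requires r > 0")
  pref <- reduced_temperature * params$charge_prefactor
  lam <- params$debye_length
  ex <- exp(-r / lam)
  inside <- r < params$elec_cutoff
  list(energy = ifelse(inside, pref * ex / r, 0),
       force = ifelse(inside, pref * ex * (1 / r^2 + 1 / (lam * r)), 0))
}

#' Total force on every bead
#'
#' Superposition of FENE bonds (consecutive pairs), bending (interior
#' triplets), excluded volume (all pairs, bonded included - the Kremer-Grest
#' convention that puts the bond minimum near 0.97 sigma), screened
#' electrostatics (nonbonded pairs, when charged), the capsid wall, tail
#' retention and the motor. Evaluated in compiled code.
#'
#' @param state a [system_state] or an N x 3 position matrix.
#' @param params an [interaction_params()].
#' @param assembly a [capsid_assembly()], or `NULL` for a free chain.
#' @param motor_on logical; apply the feeding force?
#' @param reduced_temperature T* (enters the electrostatic term).
#' @return List with `forces` (N x 3 matrix) and `energy` (total potential
#'   energy of the conservative terms; the motor force is non-conservative
#'   and carries no energy term).
#' @export
total_forces <- function(state, params = interaction_params(),
                         assembly = NULL, motor_on = FALSE,
                         reduced_temperature = 1) {
  pos <- if (inherits(state, "system_state")) state$pos else rbind_pos(state)
  geom <- if (is.null(assembly)) unclass(no_geometry()) else unclass(assembly)
  cpp_bead_forces(pos, unclass(params), geom, reduced_temperature,
                  isTRUE(motor_on))
}
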