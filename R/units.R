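# Reduced <-> physical unit mapping.
#
# The reduced system is sigma = epsilon = m = k_B = 1. The physical anchors
# are: T* = 1 corresponds to 37 C (so epsilon = k_B * 310.15 K), the capsid
# radius 3.02 sigma corresponds to 7.5 nm (so sigma = 7.5/3.02 nm ~ 2.48 nm),
# and one reduced force unit corresponds to 1.6 pN (stored as its own
# constant: the three anchors are mutually consistent only to a few percent,
# see the methods vignette).

.KB_PN_NM_PER_K <- 1.380649e-2 # Boltzmann constant, pN nm / K
.T_REF_K <- 310.15             # 37 C in kelvin

#' Reduced-unit system and physical conversions
#'
#' Defines the mapping between the simulation's reduced units and physical
#' units: one force unit = 1.6 pN (so the default motor force of 80 units is
#' 128 pN), sigma = 7.5/3.02 nm (the capsid radius 3.02 sigma corresponds to
#' 7.5 nm), and the energy unit equals k_B T at 37 C (~4.3 pN nm), with
#' reduced temperature T* = 1 mapping to 37 C.
#'
#' @param sigma_nm bead diameter in nm.
#' @param force_unit_pN physical force per reduced force unit, pN.
#' @param t_ref_K physical temperature corresponding to T* = 1, kelvin.
#' @return An object of class `unit_system`: a list with fields `sigma_nm`,
#'   `epsilon_pNnm`, `force_unit_pN`, `mass_unit`, `tau` (the reduced time
#'   unit, equal to 1 by construction) and `t_ref_K`.
#' @examples
#' u <- unit_system()
#' to_physical(80, "force", u)    # 128 pN
#' to_physical(0.75, "length", u) # ~1.9 nm
#' @export
unit_system <- function(sigma_nm = 7.5 / 3.02, force_unit_pN = 1.6,
                        t_ref_K = .T_REF_K) {
  stopifnot(sigma_nm > 0, force_unit_pN > 0, t_ref_K > 0)
  structure(
    list(
      sigma_nm = sigma_nm,
      epsilon_pNnm = .KB_PN_NM_PER_K * t_ref_K,
      force_unit_pN = force_unit_pN,
      mass_unit = 1,
      tau = 1,
      t_ref_K = t_ref_K
    ),
    class = "unit_system"
  )
}

#' @export
print.unit_system <- function(x, ...) {
  cat("Reduced-unit system (sigma = epsilon = m = k_B = 1)\n")
  cat(sprintf("  sigma      = %.4f nm\n", x$sigma_nm))
  cat(sprintf("  epsilon    = %.4f pN nm (k_B T at %.2f K)\n",
              x$epsilon_pNnm, x$t_ref_K))
  cat(sprintf("  force unit = %.2f pN\n", x$force_unit_pN))
  invisible(x)
}

.unit_kinds <- c("force", "length", "energy", "temperature")

#' Convert a reduced quantity to physical units
#'
#' Exact linear conversion using the [unit_system()] constants. Temperature
#' maps T* to degrees Celsius with T* = 1 at 37 C.
#'
#' @param value numeric vector of reduced-unit values.
#' @param kind one of `"force"` (pN), `"length"` (nm), `"energy"` (pN nm),
#'   `"temperature"` (degrees C).
#' @param units a [unit_system()].
#' @return Numeric vector of physical values, with a `"unit"` attribute
#'   carrying the unit label.
#' @export
to_physical <- function(value, kind = .unit_kinds, units = unit_system()) {
  kind <- match.arg(kind)
  out <- switch(kind,
    force = value * units$force_unit_pN,
    length = value * units$sigma_nm,
    energy = value * units$epsilon_pNnm,
    temperature = value * units$t_ref_K - 273.15
  )
  attr(out, "unit") <- switch(kind, force = "pN", length = "nm",
                              energy = "pN nm", temperature = "degC")
  out
}

#' Convert a physical quantity to reduced units
#'
#' Inverse of [to_physical()]; the round trip is the identity to machine
#' precision.
#'
#' @inheritParams to_physical
#' @param value numeric vector of physical values (pN, nm, pN nm or degC
#'   according to `kind`).
#' @return Numeric vector of reduced-unit values.
#' @export
from_physical <- function(value, kind = .unit_kinds, units = unit_system()) {
  kind <- match.arg(kind)
  switch(kind,
    force = value / units$force_unit_pN,
    length = value / units$sigma_nm,
    energy = value / units$epsilon_pNnm,
    temperature = (value + 273.15) / units$t_ref_K
  )
}

#' Bjerrum length in water
#'
#' Separation at which the Coulomb energy of two unit charges equals k_B T:
#' \eqn{l_B = e^2 / (4 \pi \epsilon_0 \epsilon_r k_B T)}. At 37 C with
#' \eqn{\epsilon_r = 80} this is about 0.7 nm, the value relevant to the
#' charged-backbone electrostatics modeled here.
#'
#' @param temperature_K absolute temperature, kelvin.
#' @param epsilon_r relative permittivity of the solvent (80 for water).
#' @return Bjerrum length in nm, computed from physical constants.
#' @export
bjerrum_length_nm <- function(temperature_K = .T_REF_K, epsilon_r = 80) {
  stopifnot(temperature_K > 0, epsilon_r > 0)
  e <- 1.602176634e-19    # elementary charge, C
  eps0 <- 8.8541878128e-12 # vacuum permittivity, F/m
  kB <- 1.380649e-23      # Boltzmann constant, J/K
  lb_m <- e^2 / (4 * pi * eps0 * epsilon_r * kB * temperature_K)
  lb_m * 1e9
}
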