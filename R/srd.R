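# Stochastic rotation dynamics (SRD/MPCD) solvent. Point particles stream
# ballistically and undergo cell-wise stochastic rotations of their
# velocities about the cell center-of-mass velocity; polymer beads join the
# collision as cell members, which is what couples chain and fluid.

#' SRD solvent parameters
#'
#' Defaults follow the standard MPCD parameterization: cell size a = 1 sigma,
#' rotation angle 130 degrees, mean density gamma = 5 particles per cell,
#' one collision every 20 MD steps, random grid shifting for Galilean
#' invariance, and solvent particle mass `1/gamma` so that one bead weighs as
#' much as the average cell content. `thermostat` enables the cell-level
#' Maxwell-Boltzmann rescaling thermostat (conserves per-cell momentum; needed
#' to absorb the motor's work in a finite box). `hydrodynamics = FALSE`
#' replaces every solvent velocity by a fresh Maxwell-Boltzmann draw after
#' each collision step, destroying hydrodynamic correlations while leaving
#' equilibrium statistics unchanged.
#'
#' @param cell_size collision cell edge, sigma.
#' @param rotation_angle_deg SRD rotation angle, degrees.
#' @param srd_interval MD steps between collision steps.
#' @param mean_density solvent particles per cell (gamma).
#' @param grid_shift logical; random grid shift each collision step.
#' @param box_edge periodic box edge, sigma (integer multiple of
#'   `cell_size`; the box is centered on the capsid).
#' @param hydrodynamics logical; `FALSE` switches on velocity resampling.
#' @param thermostat logical; cell-level MBS thermostat.
#' @return An object of class `srd_params`.
#' @export
srd_params <- function(cell_size = 1, rotation_angle_deg = 130,
                       srd_interval = 10, mean_density = 5, grid_shift = TRUE,
                       box_edge = 16, hydrodynamics = TRUE,
                       thermostat = TRUE) {
  stopifnot(cell_size > 0, rotation_angle_deg > 0, rotation_angle_deg < 180,
            srd_interval >= 1, mean_density > 0, box_edge > 0)
  if (abs(box_edge / cell_size - round(box_edge / cell_size)) > 1e-9)
    .pp_error("phagepack_invalid_value",
              "box_edge must be an integer multiple of cell_size")
  structure(
    list(cell_size = cell_size, rotation_angle_deg = rotation_angle_deg,
         srd_interval = as.integer(srd_interval),
         mean_density = mean_density, grid_shift = isTRUE(grid_shift),
         box_edge = box_edge, hydrodynamics = isTRUE(hydrodynamics),
         thermostat = isTRUE(thermostat),
         solvent_mass = 1 / mean_density),
    class = "srd_params"
  )
}

srd_from_config <- function(config) {
  s <- config$srd
  srd_params(cell_size = s$cell_size,
             rotation_angle_deg = s$rotation_angle_deg,
             srd_interval = s$srd_interval, mean_density = s$mean_density,
             grid_shift = s$grid_shift, box_edge = s$box_edge,
             hydrodynamics = config$hydrodynamics, thermostat = s$thermostat)
}

#' Initialize the solvent at a target temperature
#'
#' Places `mean_density * (box_edge/cell_size)^3` point particles uniformly
#' in the periodic box and draws velocities from the Maxwell-Boltzmann
#' distribution at `reduced_temperature`, with the net drift removed and the
#' kinetic temperature rescaled exactly to target.
#'
#' @param params an [srd_params()].
#' @param reduced_temperature target T*.
#' @param seed integer seed (a dedicated stream is derived from it).
#' @return A `solvent_state`: list with `pos`, `vel` (n x 3 matrices) and
#'   `mass`.
#' @export
init_solvent <- function(params = srd_params(), reduced_temperature = 1,
                         seed = 1) {
  n <- round(params$mean_density * (params$box_edge / params$cell_size)^3)
  st <- cpp_init_solvent(n, params$box_edge, reduced_temperature,
                         params$solvent_mass, as.double(seed), 101)
  structure(list(pos = st$pos, vel = st$vel, mass = params$solvent_mass),
            class = "solvent_state")
}

#' Stream solvent particles ballistically
#'
#' `pos <- pos + vel * dt` with periodic wrapping into the box; velocities
#' unchanged.
#'
#' @param solvent a `solvent_state`.
#' @param dt streaming time, tau.
#' @param box_edge periodic box edge.
#' @return The updated `solvent_state`.
#' @export
srd_stream <- function(solvent, dt, box_edge) {
  stopifnot(dt > 0)
  p <- solvent$pos + solvent$vel * dt
  solvent$pos <- (p + box_edge / 2) %% box_edge - box_edge / 2
  solvent
}

#' One SRD collision step
#'
#' Assigns solvent particles and beads to (optionally shifted) cells and
#' rotates every member's velocity about the cell's mass-weighted
#' center-of-mass velocity by the rotation angle about a random axis.
#' Per-cell momentum and kinetic energy are conserved exactly (the MBS
#' thermostat, when enabled, rescales relative velocities and preserves the
#' momentum but not the energy). `shift` and `axis` may be fixed for testing;
#' by default they are drawn from the collision stream.
#'
#' @param solvent a `solvent_state`.
#' @param bead_pos,bead_vel N x 3 matrices for the polymer beads (may have
#'   zero rows).
#' @param params an [srd_params()].
#' @param reduced_temperature T* (used only by the thermostat).
#' @param thermostat logical; apply the cell-level MBS thermostat.
#' @param shift optional fixed grid shift 3-vector (`NULL`: random draw, or
#'   zero when `grid_shift` is off).
#' @param axis optional fixed rotation axis (`NULL`: random per cell).
#' @param seed integer seed for the collision stream.
#' @return List with the updated `solvent` and `bead_vel`.
#' @export
srd_collide <- function(solvent, bead_pos = matrix(0, 0, 3),
                        bead_vel = matrix(0, 0, 3), params = srd_params(),
                        reduced_temperature = 1, thermostat = FALSE,
                        shift = NULL, axis = NULL, seed = 1) {
  bead_pos <- rbind_pos(bead_pos)
  if (is.null(shift) && !params$grid_shift) shift <- c(0, 0, 0)
  out <- cpp_srd_collide(solvent$pos, solvent$vel, bead_pos,
                         rbind_pos(bead_vel), params$cell_size,
                         params$box_edge, params$rotation_angle_deg,
                         solvent$mass, reduced_temperature,
                         isTRUE(thermostat), params$grid_shift,
                         shift, axis, as.double(seed), 202)
  solvent$vel <- out$svel
  list(solvent = solvent, bead_vel = out$bvel)
}

#' Draw grid-shift offsets
#'
#' Uniform offsets in `[-a/2, a/2)^3` applied to the collision-cell
#' decomposition each collision step (zero when grid shifting is disabled).
#'
#' @param params an [srd_params()].
#' @param n number of offsets to draw.
#' @param seed integer seed.
#' @return A 3 x n matrix of offsets.
#' @export
grid_shift <- function(params = srd_params(), n = 1, seed = 1) {
  if (!params$grid_shift) return(matrix(0, 3, n))
  cpp_grid_shift_draws(as.integer(n), params$cell_size, as.double(seed), 303)
}

#' Resample solvent velocities (hydrodynamics off)
#'
#' Replaces every solvent velocity component by an independent normal draw of
#' variance `T*/m`, destroying velocity correlations between collision steps
#' while leaving single-particle statics unchanged. Beads are untouched.
#'
#' @param solvent a `solvent_state`.
#' @param reduced_temperature target T*.
#' @param seed integer seed.
#' @return The updated `solvent_state`.
#' @export
resample_velocities_no_hydro <- function(solvent, reduced_temperature = 1,
                                         seed = 1) {
  solvent$vel <- cpp_resample_velocities(nrow(solvent$vel),
                                         reduced_temperature, solvent$mass,
                                         as.double(seed), 404)
  solvent
}

#' Kinetic temperature estimate
#'
#' `T* = m <v^2> / 3` per particle (reduced units, k_B = 1).
#'
#' @param velocities an n x 3 velocity matrix, or a `solvent_state` /
#'   [system_state].
#' @param mass particle mass (taken from the object when one is given).
#' @return Scalar T* estimate.
#' @export
measure_kinetic_temperature <- function(velocities, mass = 1) {
  if (inherits(velocities, "solvent_state")) {
    mass <- velocities$mass
    velocities <- velocities$vel
  } else if (inherits(velocities, "system_state")) {
    velocities <- velocities$vel
  }
  if (is.null(dim(velocities)) || nrow(velocities) < 1)
    .pp_error("phagepack_invalid_value", "need at least one particle")
  mass * sum(velocities^2) / (3 * nrow(velocities))
}
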