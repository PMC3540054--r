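# Velocity-Verlet MD for the beads and the hybrid MD <-> SRD scheduling loop.
# The hot loop lives in compiled code; these wrappers own the system_state
# container and the seed bookkeeping.

#' System state container
#'
#' Bundles the polymer bead positions and velocities, the solvent state, the
#' MD step counter and the box geometry. This is the single evolving object
#' passed through the integrator and the protocol drivers.
#'
#' @param pos,vel N x 3 bead position and velocity matrices.
#' @param solvent a `solvent_state` from [init_solvent()], or `NULL` for
#'   solvent-free integration.
#' @param step MD step counter.
#' @param dt MD time step, tau.
#' @param box_edge periodic box edge, sigma.
#' @return An object of class `system_state`.
#' @export
system_state <- function(pos, vel = NULL, solvent = NULL, step = 0,
                         dt = 0.005, box_edge = 16) {
  pos <- rbind_pos(pos)
  if (is.null(vel)) vel <- matrix(0, nrow(pos), 3)
  vel <- rbind_pos(vel)
  stopifnot(nrow(pos) == nrow(vel), all(is.finite(pos)), all(is.finite(vel)))
  structure(
    list(pos = pos, vel = vel, solvent = solvent, step = step, dt = dt,
         box_edge = box_edge, bead_mass = 1),
    class = "system_state"
  )
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("system_state: %d beads at step %g (t = %g tau)%s\n",
              nrow(x$pos), x$step, x$step * x$dt,
              if (is.null(x$solvent)) ""
              else sprintf(", %d solvent particles", nrow(x$solvent$pos))))
  invisible(x)
}

#' Velocity-Verlet integration of the beads (no solvent)
#'
#' Standard two-half-kick, one-drift update using [total_forces()]. With
#' conservative forces only (motor off) this conserves energy and momentum;
#' the returned energy trace is used by the NVE drift checks.
#'
#' @param state a [system_state()].
#' @param params an [interaction_params()].
#' @param assembly a [capsid_assembly()] or `NULL`.
#' @param motor_on logical; apply the feeding force?
#' @param dt MD time step, tau.
#' @param n_steps number of steps.
#' @param reduced_temperature T* (electrostatic scaling).
#' @param energy_stride record the total energy every this many steps.
#' @return The advanced `system_state`, with attribute `"energies"` holding
#'   the sampled total (kinetic + potential) energy trace.
#' @export
velocity_verlet_step <- function(state, params = interaction_params(),
                                 assembly = NULL, motor_on = FALSE,
                                 dt = state$dt, n_steps = 1,
                                 reduced_temperature = 1,
                                 energy_stride = 0) {
  stopifnot(dt > 0, n_steps >= 0)
  if (n_steps == 0) return(state)
  geom <- if (is.null(assembly)) unclass(no_geometry()) else unclass(assembly)
  out <- cpp_velocity_verlet(state$pos, state$vel, unclass(params), geom,
                             reduced_temperature, isTRUE(motor_on), dt,
                             as.double(n_steps), as.double(energy_stride))
  state$pos <- out$pos
  state$vel <- out$vel
  state$step <- state$step + n_steps
  state$dt <- dt
  attr(state, "energies") <- out$energies
  state
}

#' Advance the hybrid MD/SRD system
#'
#' Repeats [`srd_interval` MD bead steps + ballistic solvent streaming over
#' the same interval + one collision step (with optional grid shift, MBS
#' thermostat, and - when hydrodynamics are off - solvent velocity
#' resampling)] until `n_steps` MD steps have elapsed. Deterministic for a
#' fixed `(config, seed)`.
#'
#' @param state a [system_state()] with a solvent.
#' @param config a [sim_config()].
#' @param n_steps number of MD steps to advance.
#' @param motor_on logical; feeding force active?
#' @param seed integer seed for the collision/thermostat stream.
#' @param anchor index of a bead to hold fixed (NA: none).
#' @param sample_stride record occupancy every this many steps (default: the
#'   config's `sampling_stride`).
#' @param stop_on `"none"`, `"packed"` (all bead centers inside the capsid
#'   sphere) or `"ejected"` (no bead center inside capsid, pore or tail).
#' @return The advanced `system_state`; attributes `"timeseries"` (data frame
#'   step/beads_inside/beads_in_tail), `"event_step"` (NA unless a stop
#'   condition fired) and `"mean_T"` (run-averaged bead and solvent kinetic
#'   temperatures).
#' @export
hybrid_advance <- function(state, config, n_steps, motor_on = FALSE,
                           seed = config$seed, anchor = NA,
                           sample_stride = config$sampling_stride,
                           stop_on = c("none", "packed", "ejected")) {
  stop_on <- match.arg(stop_on)
  stopifnot(n_steps >= 0)
  if (n_steps == 0) return(state)
  if (is.null(state$solvent))
    .pp_error("phagepack_invalid_value",
              "hybrid_advance needs a solvent; use velocity_verlet_step")
  params <- params_from_config(config)
  assembly <- assembly_from_config(config)
  srd <- srd_from_config(config)
  srd_list <- unclass(srd)
  srd_list$box_edge <- state$box_edge
  out <- cpp_run(state$pos, state$vel, state$solvent$pos, state$solvent$vel,
                 unclass(params), unclass(assembly), srd_list,
                 config$reduced_temperature, state$dt, as.double(n_steps),
                 isTRUE(motor_on), config$hydrodynamics,
                 as.double(sample_stride),
                 switch(stop_on, none = 0L, packed = 1L, ejected = 2L),
                 if (is.na(anchor)) -1L else as.integer(anchor) - 1L,
                 as.double(seed), 1)
  state$pos <- out$pos
  state$vel <- out$vel
  state$solvent$pos <- out$spos
  state$solvent$vel <- out$svel
  start_step <- state$step
  state$step <- state$step + out$steps_done
  attr(state, "timeseries") <- data.frame(
    step = start_step + out$ts_step,
    beads_inside = as.integer(out$ts_inside),
    beads_in_tail = as.integer(out$ts_tail)
  )
  attr(state, "event_step") <-
    if (out$event_step < 0) NA_real_ else start_step + out$event_step
  attr(state, "mean_T") <- c(beads = out$mean_T_beads,
                             solvent = out$mean_T_solvent)
  state
}
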