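# Validated run configuration. A sim_config is a nested list of four blocks
# (top-level run controls + interaction/geometry/srd parameter blocks), each
# key with a documented default, checked on construction.

.pp_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "phagepack_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Default configuration values
#'
#' Returns the full default configuration as a nested list; every key of a
#' [sim_config()] with its default in reduced units. Tunables whose values the
#' model calibrates rather than fixes a priori (`bend_kappa`, targeted at a
#' 10-sigma persistence length, and `charge_prefactor`, set so that a charged
#' chain packs fully at T* = 1.0 but stalls at T* = 1.2 in a tailless capsid)
#' are documented in the methods vignette.
#'
#' @return Nested list of defaults.
#' @export
config_defaults <- function() {
  list(
    reduced_temperature = 1.0, # T*; 1.0 corresponds to 37 C
    n_beads = 100L,            # chain length N
    charged = FALSE,           # Debye-Hueckel backbone electrostatics
    tail_present = FALSE,      # cylindrical tail on the capsid pore
    hydrodynamics = TRUE,      # FALSE: resample solvent velocities each collision
    motor_force = 80,          # constant feeding force, reduced units (128 pN)
    equilibration_steps = 1e5, # MD steps with motor off, anchor bead pinned
    max_steps = 2e6,           # hard budget per run ("timeout" when exceeded)
    sampling_stride = 1000,    # MD steps between occupancy samples
    n_replicates = 100L,       # ensemble size
    seed = 1L,                 # master seed; replicate seeds derived from it
    interaction = list(
      fene_k = 30,             # FENE spring strength, epsilon/sigma^2
      fene_r0 = 1.5,           # maximum bond extension, sigma
      lj_epsilon = 1,          # excluded-volume energy scale
      lj_sigma = 1,            # bead diameter
      lj_cutoff = 2^(1 / 6),   # WCA cutoff: purely repulsive (good solvent)
      bend_kappa = 10.18,      # bending constant; calibrated to l_p ~ 10 sigma
      charge_prefactor = 64,   # reduced l_B Z^2; calibrated (see vignette)
      debye_length = 0.75,     # Debye screening length, sigma (1.9 nm)
      elec_cutoff = 3          # electrostatic cutoff, 4 x debye_length
    ),
    geometry = list(
      capsid_radius = 3.02,    # sphere radius, sigma (7.5 nm)
      pore_radius = 0.6,       # admits one bead cross-section at a time
      wall_stiffness = 800,    # linear wall repulsion; max force (stiffness x range)
                               # must exceed the motor force so the shell is
                               # impenetrable under drive
      wall_range = 0.5,        # half-thickness of the repulsive shell, sigma
      tail_length = 6,         # tail cylinder length, sigma
      tail_radius = 0.7,       # tail cylinder radius, sigma (single-file)
      tail_stiffness = 800,    # retention force constant, epsilon/sigma^2
      motor_capture_radius = 1.25 # capture sphere covering the funnel mouth, sigma
    ),
    srd = list(
      cell_size = 1,           # collision cell edge a, sigma
      rotation_angle_deg = 130,# SRD rotation angle
      srd_interval = 10,       # MD steps between collision steps (keeps the
                               # motor free-flight velocity gain ~2x thermal)
      mean_density = 5,        # solvent particles per cell (gamma)
      grid_shift = TRUE,       # random grid shift (Galilean invariance)
      box_edge = 16,           # periodic box edge, sigma
      thermostat = TRUE        # cell-level MBS thermostat (absorbs motor work)
    ),
    integrator = list(
      dt = 0.005               # MD time step, tau
    )
  )
}

.flag_keys <- c("charged", "tail_present", "hydrodynamics")

.validate_config <- function(cfg) {
  if (!is.numeric(cfg$reduced_temperature) || cfg$reduced_temperature <= 0)
    .pp_error("phagepack_invalid_value",
              "reduced_temperature must be positive (got %s)",
              format(cfg$reduced_temperature))
  if (cfg$n_beads < 3)
    .pp_error("phagepack_invalid_value", "n_beads must be >= 3 (got %d)",
              cfg$n_beads)
  if (cfg$motor_force < 0)
    .pp_error("phagepack_invalid_value", "motor_force must be >= 0 (got %s)",
              format(cfg$motor_force))
  if (!(cfg$max_steps > cfg$equilibration_steps) || cfg$equilibration_steps <= 0)
    .pp_error("phagepack_invalid_value",
              "need max_steps > equilibration_steps > 0")
  for (k in .flag_keys)
    if (!is.logical(cfg[[k]]) || is.na(cfg[[k]]))
      .pp_error("phagepack_invalid_value", "%s must be TRUE or FALSE", k)
  with(cfg$interaction, {
    if (fene_r0 <= 1 || fene_k < 0 || bend_kappa < 0 || charge_prefactor < 0)
      .pp_error("phagepack_invalid_value", "invalid interaction block")
    if (elec_cutoff <= debye_length)
      .pp_error("phagepack_invalid_value",
                "elec_cutoff must exceed debye_length")
  })
  with(cfg$geometry, {
    if (capsid_radius <= 0 || pore_radius <= 0 || pore_radius >= 1)
      .pp_error("phagepack_invalid_value",
                "pore_radius must lie in (0, 1) sigma (single-bead pore)")
    if (tail_radius >= 1 || tail_length <= 0)
      .pp_error("phagepack_invalid_value", "invalid tail geometry")
  })
  with(cfg$srd, {
    if (cell_size <= 0 || rotation_angle_deg <= 0 || rotation_angle_deg >= 180)
      .pp_error("phagepack_invalid_value", "invalid srd block")
    if (abs(box_edge / cell_size - round(box_edge / cell_size)) > 1e-9)
      .pp_error("phagepack_invalid_value",
                "box_edge must be an integer multiple of cell_size")
  })
  if (cfg$integrator$dt <= 0)
    .pp_error("phagepack_invalid_value", "dt must be positive")
  cfg
}

#' Build a validated simulation configuration
#'
#' Constructs the full run configuration, starting from [config_defaults()]
#' and applying any overrides given as named arguments. Nested block values
#' are overridden by passing partial lists, e.g.
#' `sim_config(interaction = list(bend_kappa = 5))`.
#'
#' @param ... named overrides of the keys in [config_defaults()].
#' @return An object of class `sim_config` (validated nested list).
#' @examples
#' cfg <- sim_config(reduced_temperature = 1.2, charged = TRUE, n_beads = 40)
#' @export
sim_config <- function(...) {
  over <- list(...)
  cfg <- config_defaults()
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    .pp_error("phagepack_unknown_key", "unknown configuration key(s): %s",
              paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]])) {
      if (!is.list(over[[nm]]))
        .pp_error("phagepack_malformed_key", "'%s' must be a list block", nm)
      badk <- setdiff(names(over[[nm]]), names(cfg[[nm]]))
      if (length(badk))
        .pp_error("phagepack_unknown_key", "unknown key(s) in '%s': %s", nm,
                  paste(badk, collapse = ", "))
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  cfg$n_beads <- as.integer(cfg$n_beads)
  cfg$n_replicates <- as.integer(cfg$n_replicates)
  cfg$seed <- as.integer(cfg$seed)
  structure(.validate_config(cfg), class = "sim_config")
}

#' Scaled-down study configuration
#'
#' Reference conditions for desk-scale experiments: a shorter chain in a
#' capsid whose radius is reduced to preserve the full-scale packing
#' fraction (~0.45 for 100 beads in a 3.02-sigma sphere), a smaller periodic
#' box, and reduced step budgets. The confinement physics (crowding,
#' electrostatic resistance, bending stress) is controlled by the packing
#' fraction, so scaling the radius with `n_beads^(1/3)` keeps the scaled
#' experiments in the same regime as the full-size system.
#'
#' @param n_beads chain length (default 40).
#' @param ... further overrides passed to [sim_config()].
#' @return A [sim_config()] with `capsid_radius = 3.02 (n_beads/100)^(1/3)`,
#'   box edge 12 sigma, and reduced step budgets.
#' @export
scaled_config <- function(n_beads = 40L, ...) {
  base <- list(
    n_beads = as.integer(n_beads),
    equilibration_steps = 5000,
    max_steps = 3e5,
    sampling_stride = 5000,
    n_replicates = 10L,
    geometry = list(capsid_radius = round(3.02 * (n_beads / 100)^(1 / 3), 2)),
    srd = list(box_edge = 12)
  )
  do.call(sim_config, modifyList(base, list(...)))
}

#' Load a configuration from a YAML file
#'
#' Reads a flat or block-nested YAML file of configuration keys (any subset;
#' unspecified keys take the documented defaults) and returns a validated
#' [sim_config()].
#'
#' @param path path to a YAML configuration file.
#' @return A validated `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    .pp_error("phagepack_missing_file", "config file not found: %s", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    .pp_error("phagepack_malformed_key", "cannot parse config file %s: %s",
              path, conditionMessage(e)))
  if (is.null(raw)) raw <- list()
  if (!is.list(raw) || (length(raw) && is.null(names(raw))))
    .pp_error("phagepack_malformed_key", "config file must be a key-value map")
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: N = %d beads, T* = %g, %s, %s, hydrodynamics %s\n",
    x$n_beads, x$reduced_temperature,
    if (x$charged) "charged" else "neutral",
    if (x$tail_present) "tail" else "tailless",
    if (x$hydrodynamics) "on" else "off"
  ))
  cat(sprintf("  motor force %g (%.0f pN), equil %g / max %g MD steps, %d replicate(s), seed %d\n",
              x$motor_force, to_physical(x$motor_force, "force"),
              x$equilibration_steps, x$max_steps, x$n_replicates, x$seed))
  invisible(x)
}

# Derive a reproducible child seed (31-bit, for both R and C++ streams) from
# a master seed and a stream label.
derive_seed <- function(master, stream) {
  as.integer(cpp_derive_seed(as.double(master), as.double(stream)))
}
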