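# Capsid assembly: rigid sphere with a single-bead pore on +z, optional
# cylindrical tail attached to the pore, and the constant-force motor. All
# geometry-derived forces act on polymer beads only; the capsid is permeable
# to the solvent.

#' Capsid assembly: sphere, pore, optional tail, motor
#'
#' The capsid is a rigid sphere of radius `capsid_radius` centered at the
#' origin with its pore on the +z axis at `(0, 0, capsid_radius)`. Beads are
#' repelled from the wall on both sides by a linear force of stiffness
#' `wall_stiffness` acting within a shell of half-thickness `wall_range`,
#' suppressed inside the pore channel so the chain can pass. The optional
#' tail is a cylinder of length `tail_length` and radius `tail_radius`
#' attached to the pore; a bead in its sheath is pulled back toward
#' the lumen with force `tail_stiffness * excess` once its radial distance
#' exceeds `tail_radius` (see [tail_retention_force()]). The motor applies a constant force of
#' magnitude `motor_force` directed toward the capsid center to every bead
#' within `motor_capture_radius` of the pore mouth.
#'
#' @param capsid_radius sphere radius, sigma.
#' @param pore_radius pore channel radius, sigma; must be < 1 (one bead at a
#'   time).
#' @param wall_stiffness,wall_range wall repulsion constant and shell
#'   half-thickness.
#' @param tail logical; attach the tail cylinder?
#' @param tail_length,tail_radius,tail_stiffness tail geometry and retention
#'   stiffness.
#' @param motor_force constant feeding force, reduced units.
#' @param motor_capture_radius radius of the capture sphere at the pore mouth.
#' @return An object of class `capsid_assembly`.
#' @examples
#' asm <- capsid_assembly(tail = TRUE)
#' classify_position(c(0, 0, 3.02 + 3), asm)  # "in_tail"
#' @export
capsid_assembly <- function(capsid_radius = 3.02, pore_radius = 0.6,
                            wall_stiffness = 800, wall_range = 0.5,
                            tail = FALSE, tail_length = 6, tail_radius = 0.7,
                            tail_stiffness = 800, motor_force = 80,
                            motor_capture_radius = 1.25) {
  stopifnot(capsid_radius > 0, pore_radius > 0, pore_radius < 1,
            wall_stiffness >= 0, wall_range > 0, tail_length > 0,
            tail_radius > 0, tail_radius < 1, motor_force >= 0,
            motor_capture_radius > 0)
  structure(
    list(enabled = TRUE, capsid_radius = capsid_radius,
         pore_radius = pore_radius, wall_stiffness = wall_stiffness,
         wall_range = wall_range, tail = tail, tail_length = tail_length,
         tail_radius = tail_radius, tail_stiffness = tail_stiffness,
         motor_force = motor_force,
         motor_capture_radius = motor_capture_radius),
    class = "capsid_assembly"
  )
}

# assembly from a sim_config (motor magnitude and tail flag live at top level)
assembly_from_config <- function(config) {
  g <- config$geometry
  capsid_assembly(
    capsid_radius = g$capsid_radius, pore_radius = g$pore_radius,
    wall_stiffness = g$wall_stiffness, wall_range = g$wall_range,
    tail = config$tail_present, tail_length = g$tail_length,
    tail_radius = g$tail_radius, tail_stiffness = g$tail_stiffness,
    motor_force = config$motor_force,
    motor_capture_radius = g$motor_capture_radius
  )
}

# sentinel "no geometry" assembly for free chains
no_geometry <- function() {
  structure(list(enabled = FALSE), class = "capsid_assembly")
}

#' @export
print.capsid_assembly <- function(x, ...) {
  if (!x$enabled) {
    cat("capsid_assembly: disabled (free chain)\n")
    return(invisible(x))
  }
  cat(sprintf("capsid_assembly: sphere R = %g sigma, pore radius %g on +z\n",
              x$capsid_radius, x$pore_radius))
  if (x$tail)
    cat(sprintf("  tail: length %g, radius %g, retention stiffness %g\n",
                x$tail_length, x$tail_radius, x$tail_stiffness))
  cat(sprintf("  motor: %g force units within %g sigma of the pore mouth\n",
              x$motor_force, x$motor_capture_radius))
  invisible(x)
}

.region_labels <- c("inside_capsid", "in_pore", "in_tail", "outside")

#' Classify positions relative to the capsid assembly
#'
#' Deterministically partitions space into `inside_capsid`, `in_pore`
#' (the channel through the wall shell), `in_tail` (only when the tail is
#' present) and `outside`.
#'
#' @param pos a 3-vector or an n x 3 matrix of positions.
#' @param assembly a [capsid_assembly()].
#' @return Character vector of region labels, one per position.
#' @export
classify_position <- function(pos, assembly) {
  pos <- rbind_pos(pos)
  .region_labels[cpp_classify(pos, unclass(assembly)) + 1L]
}

rbind_pos <- function(pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 3, byrow = TRUE)
  storage.mode(pos) <- "double"
  pos
}

#' Capsid wall force on a bead
#'
#' Zero outside the repulsive shell around the sphere surface; inside the
#' shell the force is radial with magnitude `wall_stiffness * penetration`,
#' pushing inside beads inward and outside beads outward, and is suppressed
#' in the pore channel.
#'
#' @inheritParams classify_position
#' @param pos a single 3-vector position.
#' @return Force 3-vector (with the conservative energy as attribute
#'   `"energy"`).
#' @export
wall_force <- function(pos, assembly) {
  stopifnot(length(pos) == 3)
  a <- unclass(assembly)
  a$tail <- FALSE
  a$motor_force <- 0
  cpp_geometry_force(as.double(pos), a, FALSE)
}

#' Tail retention force on a bead
#'
#' The tail is a tube with an open lumen of radius `tail_radius` wrapped in
#' a thick sheath (two bead diameters, so the chain can neither span nor
#' hang over it). A bead inside the sheath is pushed toward the nearer free
#' region: on the lumen side this is the retention law - a pull toward the
#' axis of magnitude `tail_stiffness * (rho - tail_radius)`, saturating at
#' half-sigma penetration - and on the outer side the mirror-image
#' repulsion off the tube. The sheath softens over its last sigma below the
#' tip (the open end), and extends down through the capsid wall shell so
#' lumen and pore line up. Beads outside the sheath or beyond the tail's
#' axial extent feel nothing.
#'
#' @inheritParams wall_force
#' @return Force 3-vector (energy as attribute `"energy"`).
#' @export
tail_retention_force <- function(pos, assembly) {
  stopifnot(length(pos) == 3)
  if (!isTRUE(assembly$tail))
    .pp_error("phagepack_invalid_value", "assembly has no tail")
  a <- unclass(assembly)
  a$wall_stiffness <- 0
  a$motor_force <- 0
  cpp_geometry_force(as.double(pos), a, FALSE)
}

#' Motor force on a bead
#'
#' Constant force of magnitude `motor_force` directed from the bead toward
#' the capsid center, applied to every bead inside the capture sphere at the
#' pore mouth; identically zero when `motor_on` is `FALSE` (ejection mode).
#'
#' @inheritParams wall_force
#' @param motor_on logical; feeding force active?
#' @return Force 3-vector.
#' @export
motor_force <- function(pos, assembly, motor_on = TRUE) {
  stopifnot(length(pos) == 3)
  a <- unclass(assembly)
  a$wall_stiffness <- 0
  a$tail <- FALSE
  f <- cpp_geometry_force(as.double(pos), a, isTRUE(motor_on))
  attr(f, "energy") <- NULL
  f
}

#' Count beads inside the capsid and in the tail
#'
#' @param state a [system_state] (or an n x 3 position matrix).
#' @param assembly a [capsid_assembly()].
#' @return Named integer vector `c(inside = ..., tail = ...)`; the remaining
#'   beads are in the pore or outside.
#' @export
count_occupancy <- function(state, assembly) {
  pos <- if (inherits(state, "system_state")) state$pos else rbind_pos(state)
  reg <- classify_position(pos, assembly)
  c(inside = sum(reg == "inside_capsid"), tail = sum(reg == "in_tail"))
}
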