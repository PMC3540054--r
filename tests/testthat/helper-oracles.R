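# Shared oracles and fixtures, all built in code.

# central finite difference of a scalar energy function
fd_gradient <- function(energy_fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (energy_fn(xp) - energy_fn(xm)) / (2 * h)
  }, numeric(1))
}

# independent R-level superposition of all conservative terms, assembled from
# the exported scalar potentials; cross-checks the compiled total_forces()
r_reference_energy <- function(pos, params, assembly = NULL,
                               reduced_temperature = 1) {
  n <- nrow(pos)
  U <- 0
  for (i in seq_len(n - 1)) {
    r <- sqrt(sum((pos[i, ] - pos[i + 1, ])^2))
    U <- U + fene_bond(r, params)$energy
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      U <- U + excluded_volume(r, params)$energy
      if (params$charged && j > i + 1)
        U <- U + electrostatic(r, reduced_temperature, params)$energy
    }
  }
  if (params$bend_kappa > 0 && n >= 3) {
    for (j in 2:(n - 1))
      U <- U + bending(pos[(j - 1):(j + 1), , drop = FALSE], params)$energy
  }
  if (!is.null(assembly)) {
    for (i in seq_len(n)) {
      U <- U + attr(wall_force(pos[i, ], assembly), "energy")
      if (isTRUE(assembly$tail))
        U <- U + attr(tail_retention_force(pos[i, ], assembly), "energy")
    }
    # bonds carry excluded volume against the wall: interior sample points,
    # with the wider vestibule suppression channel around the pore
    asm_mid <- assembly
    asm_mid$pore_radius <- if (isTRUE(assembly$tail)) 0.45
                           else assembly$pore_radius + 0.6
    for (i in seq_len(n - 1))
      for (t in (1:5) / 6) {
        sp <- (1 - t) * pos[i, ] + t * pos[i + 1, ]
        U <- U + attr(wall_force(sp, asm_mid), "energy")
        if (isTRUE(assembly$tail))
          U <- U + attr(tail_retention_force(sp, assembly), "energy")
      }
  }
  U
}

# random mildly-perturbed chain with bonds near the equilibrium length
random_chain <- function(n, seed, spread = 0.08) {
  set.seed(seed)
  dirs <- matrix(rnorm(3 * (n - 1)), n - 1, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # persistent-ish walk to avoid hard core overlaps
  for (i in seq_len(n - 2) + 1)
    dirs[i, ] <- {
      d <- 0.8 * dirs[i - 1, ] + 0.6 * dirs[i, ]
      d / sqrt(sum(d^2))
    }
  steps <- dirs * (0.97 + runif(n - 1, -spread, spread))
  rbind(0, apply(steps, 2, cumsum))
}

# fabricated run_record with a constant occupancy curve (aggregation oracle)
constant_record <- function(value, n_points = 5, stride = 10, id = 1,
                            n_beads = 40, max_steps = stride * (n_points - 1)) {
  structure(
    list(replicate_id = id, mode = "packing",
         timeseries = data.frame(step = seq(0, by = stride,
                                            length.out = n_points),
                                 beads_inside = rep(value, n_points),
                                 beads_in_tail = rep(0L, n_points)),
         event_time = NA_real_, status = "timeout", seed = 1,
         config_hash = "x", max_steps = max_steps, n_beads = n_beads,
         dt = 0.005, final_pos = matrix(0, 0, 3), mean_T = c(NA, NA)),
    class = "run_record"
  )
}

# small, fast configuration used throughout the unit tests
test_config <- function(...) {
  base <- list(
    n_beads = 20L,
    equilibration_steps = 2000,
    max_steps = 20000,
    sampling_stride = 500,
    n_replicates = 2L,
    srd = list(box_edge = 8)
  )
  do.call(sim_config, utils::modifyList(base, list(...)))
}
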