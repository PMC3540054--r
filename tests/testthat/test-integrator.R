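test_that("velocity Verlet is a fixed point at zero force and velocity", {
  st <- system_state(matrix(c(0, 0, 0), 1, 3))
  p0 <- interaction_params(fene_k = 0, bend_kappa = 0)
  st2 <- velocity_verlet_step(st, p0, n_steps = 50)
  expect_equal(st2$pos, st$pos)
  expect_equal(st2$vel, st$vel)
  expect_equal(st2$step, 50)
  expect_identical(velocity_verlet_step(st, p0, n_steps = 0), st)
})

test_that("a single bead under the constant motor force is ballistic", {
  asm <- capsid_assembly(motor_capture_radius = 5)
  p0 <- interaction_params(fene_k = 0, bend_kappa = 0)
  start <- c(0, 0, asm$capsid_radius + 0.8)  # outside wall shell, in capture
  st <- system_state(matrix(start, 1, 3))
  dt <- 0.002
  n <- 60
  st2 <- velocity_verlet_step(st, p0, asm, motor_on = TRUE, dt = dt,
                              n_steps = n)
  t_tot <- n * dt
  expected_z <- start[3] - 0.5 * 80 * t_tot^2  # F/m = 80 toward the center
  expect_equal(st2$pos[1, 3], expected_z, tolerance = 1e-3)
  expect_equal(st2$pos[1, 1:2], c(0, 0), tolerance = 1e-12)
})

test_that("NVE energy drift of an isolated chain is below 1e-4 relative", {
  # equilibrated thermal start; drift = secular shift of block-averaged
  # total energy (the symplectic integrator oscillates but must not drift)
  p <- interaction_params()
  conf <- sample_free_chain(20, p, 1.0, n_conformations = 1, stride = 100,
                            n_equil = 8000, seed = 31)
  set.seed(32)
  vel <- matrix(rnorm(60, sd = 1), 20, 3)
  st2 <- velocity_verlet_step(system_state(conf[, , 1], vel), p, dt = 0.005,
                              n_steps = 1e4, energy_stride = 100)
  en <- attr(st2, "energies")
  n <- length(en)
  drift <- abs(mean(en[(n %/% 2 + 1):n]) - mean(en[1:(n %/% 2)])) / abs(en[1])
  expect_lt(drift, 1e-4)
  # and even the instantaneous deviation stays small
  expect_lt(max(abs(en - en[1]) / abs(en[1])), 1e-3)
})

test_that("momentum is conserved exactly without solvent coupling", {
  pos <- random_chain(15, seed = 41)
  set.seed(42)
  vel <- matrix(rnorm(45), 15, 3)
  p_before <- colSums(vel)
  st <- velocity_verlet_step(system_state(pos, vel),
                             interaction_params(charged = TRUE),
                             n_steps = 2000)
  expect_equal(colSums(st$vel), p_before, tolerance = 1e-10)
})

test_that("hybrid advance is deterministic under the seed and 0 steps is identity", {
  cfg <- test_config()
  st <- build_initial_packing_state(cfg, seed = 5)
  expect_identical(hybrid_advance(st, cfg, 0), st)
  a <- hybrid_advance(st, cfg, 500, seed = 7)
  b <- hybrid_advance(st, cfg, 500, seed = 7)
  expect_identical(a$pos, b$pos)
  expect_identical(a$vel, b$vel)
  expect_identical(a$solvent$vel, b$solvent$vel)
  c_ <- hybrid_advance(st, cfg, 500, seed = 8)
  expect_false(identical(a$pos, c_$pos))
})

test_that("the SRD bath thermostats a free chain to the target temperature", {
  cfg <- sim_config(n_beads = 20L, equilibration_steps = 1000,
                    max_steps = 1e5, reduced_temperature = 1.0,
                    srd = list(box_edge = 8),
                    geometry = list(capsid_radius = 0.5))
  # free chain: start far from any geometry, no motor
  pos <- random_chain(20, seed = 51)
  pos[, 3] <- pos[, 3] - mean(pos[, 3]) - 2.5  # keep clear of the capsid
  sol <- init_solvent(phagepack:::srd_from_config(cfg), 1.0, seed = 52)
  st <- system_state(pos, solvent = sol, box_edge = 8)
  st2 <- hybrid_advance(st, cfg, 4e4, motor_on = FALSE, seed = 53)
  mt <- attr(st2, "mean_T")
  expect_equal(unname(mt["beads"]), 1.0, tolerance = 0.05)
  expect_equal(unname(mt["solvent"]), 1.0, tolerance = 0.02)
})

test_that("overstretched bonds raise an instability error naming the bead", {
  st <- system_state(rbind(c(0, 0, 0), c(1.49, 0, 0)),
                     rbind(c(-8, 0, 0), c(8, 0, 0)))
  expect_error(velocity_verlet_step(st, interaction_params(), n_steps = 100),
               "bead")
})
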