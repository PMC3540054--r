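sp <- srd_params(box_edge = 4, mean_density = 5)

test_that("streaming is ballistic with periodic wrapping", {
  sol <- init_solvent(sp, 1, seed = 1)
  still <- sol
  still$vel[] <- 0
  expect_equal(srd_stream(still, 0.5, sp$box_edge)$pos, still$pos)

  one <- list(pos = matrix(c(0, 0, 0), 1, 3),
              vel = matrix(c(1, 0, 0), 1, 3), mass = sp$solvent_mass)
  class(one) <- "solvent_state"
  expect_equal(srd_stream(one, 0.1, 4)$pos[1, ], c(0.1, 0, 0))
  # exits the +x face, re-enters at -x
  edge <- one
  edge$pos[1, 1] <- 1.95
  expect_equal(srd_stream(edge, 0.1, 4)$pos[1, 1], -1.95)
})

test_that("collision conserves momentum and kinetic energy per construction", {
  sol <- init_solvent(sp, 1.0, seed = 3)
  bpos <- matrix(runif(6 * 3, -1.5, 1.5), 6, 3)
  bvel <- matrix(rnorm(6 * 3), 6, 3)
  p_before <- sp$solvent_mass * colSums(sol$vel) + colSums(bvel)
  k_before <- 0.5 * sp$solvent_mass * sum(sol$vel^2) + 0.5 * sum(bvel^2)
  out <- srd_collide(sol, bpos, bvel, sp, thermostat = FALSE, seed = 5)
  p_after <- sp$solvent_mass * colSums(out$solvent$vel) + colSums(out$bead_vel)
  k_after <- 0.5 * sp$solvent_mass * sum(out$solvent$vel^2) +
    0.5 * sum(out$bead_vel^2)
  expect_equal(p_after, p_before, tolerance = 1e-12)
  expect_equal(k_after, k_before, tolerance = 1e-12)
})

test_that("MBS thermostat preserves momentum while regulating energy", {
  sol <- init_solvent(sp, 1.0, seed = 4)
  sol$vel <- sol$vel * 2  # overheated bath
  p_before <- colSums(sol$vel)
  out <- srd_collide(sol, params = sp, reduced_temperature = 1,
                     thermostat = TRUE, seed = 6)
  expect_equal(colSums(out$solvent$vel), p_before, tolerance = 1e-10)
  expect_lt(measure_kinetic_temperature(out$solvent),
            measure_kinetic_temperature(sol))
})

test_that("a lone particle in its cell is unchanged by collision", {
  lone <- list(pos = matrix(c(0.2, 0.2, 0.2), 1, 3),
               vel = matrix(c(0.4, -0.1, 0.9), 1, 3), mass = 1)
  class(lone) <- "solvent_state"
  p1 <- srd_params(box_edge = 4, mean_density = 1)
  out <- srd_collide(lone, params = p1, thermostat = FALSE,
                     shift = c(0, 0, 0), seed = 9)
  expect_equal(out$solvent$vel, lone$vel, tolerance = 1e-12)
})

test_that("two-particle collision matches the hand-computed rotation", {
  # both particles in one cell, fixed axis z, angle 130 deg
  sol <- list(pos = matrix(c(0.1, 0.1, 0.1, 0.3, 0.3, 0.3), 2, 3,
                           byrow = TRUE),
              vel = matrix(c(1, 0, 0, -1, 0, 0), 2, 3, byrow = TRUE),
              mass = 1)
  class(sol) <- "solvent_state"
  p1 <- srd_params(box_edge = 4, mean_density = 1, cell_size = 1)
  out <- srd_collide(sol, params = p1, thermostat = FALSE,
                     shift = c(0, 0, 0), axis = c(0, 0, 1), seed = 1)
  a <- 130 * pi / 180
  rot <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                byrow = TRUE)
  # vcm = 0, so each relative velocity is just rotated
  expect_equal(out$solvent$vel[1, ], as.numeric(rot %*% c(1, 0, 0)),
               tolerance = 1e-12)
  expect_equal(out$solvent$vel[2, ], as.numeric(rot %*% c(-1, 0, 0)),
               tolerance = 1e-12)
})

test_that("grid shift draws are uniform, seeded, and off when disabled", {
  off <- srd_params(box_edge = 4, grid_shift = FALSE)
  expect_equal(grid_shift(off, n = 3), matrix(0, 3, 3))
  d1 <- grid_shift(sp, n = 2000, seed = 11)
  d2 <- grid_shift(sp, n = 2000, seed = 11)
  expect_identical(d1, d2)
  expect_true(all(d1 >= -0.5 & d1 < 0.5))
  ks <- suppressWarnings(stats::ks.test(d1[1, ], "punif", -0.5, 0.5))
  expect_gt(ks$p.value, 0.001)
})

test_that("no-hydrodynamics resampling restores T* and kills correlations", {
  sol <- init_solvent(srd_params(box_edge = 8), 0.8, seed = 21)
  res <- resample_velocities_no_hydro(sol, 0.8, seed = 22)
  expect_equal(measure_kinetic_temperature(res), 0.8, tolerance = 0.02)
  res2 <- resample_velocities_no_hydro(res, 0.8, seed = 23)
  n <- nrow(res$vel)
  rho <- cor(as.vector(res$vel), as.vector(res2$vel))
  expect_lt(abs(rho), 3 / sqrt(3 * n))
})

test_that("kinetic temperature estimator matches hand arithmetic", {
  expect_equal(measure_kinetic_temperature(matrix(0, 4, 3)), 0)
  v <- matrix(c(1, 0, 0, 0, 2, 0), 2, 3, byrow = TRUE)
  expect_equal(measure_kinetic_temperature(v, mass = 2), 2 * 5 / 6)
  expect_error(measure_kinetic_temperature(matrix(0, 0, 3)),
               class = "phagepack_invalid_value")
})
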