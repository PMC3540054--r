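prm <- interaction_params()
prmQ <- interaction_params(charged = TRUE)

test_that("FENE bond matches its closed form and diverges at R0", {
  expect_equal(fene_bond(0)$energy, 0)
  expect_equal(fene_bond(0)$force, 0)
  expect_equal(fene_bond(0.97)$energy,
               -0.5 * 30 * 1.5^2 * log(1 - (0.97 / 1.5)^2))
  expect_equal(round(fene_bond(0.97)$energy, 2), 18.28)
  expect_error(fene_bond(1.5), class = "phagepack_overstretched_bond")
  expect_error(fene_bond(2.0), class = "phagepack_overstretched_bond")
})

test_that("excluded volume is the truncated-shifted LJ with WCA defaults", {
  rc <- 2^(1 / 6)
  expect_equal(excluded_volume(rc)$energy, 0, tolerance = 1e-12)
  expect_equal(excluded_volume(rc)$force, 0, tolerance = 1e-9)
  expect_equal(excluded_volume(1)$energy, 1)   # 4(1 - 1) + shift = epsilon
  expect_equal(excluded_volume(5)$energy, 0)
  expect_gt(excluded_volume(0.95)$force, 0)    # purely repulsive
  expect_error(excluded_volume(0), class = "phagepack_singularity")
})

test_that("bending energy/forces behave at the limits", {
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  b <- bending(collinear, prm)
  expect_equal(b$energy, 0, tolerance = 1e-12)
  expect_equal(max(abs(b$forces)), 0, tolerance = 1e-12)
  right <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(bending(right, prm)$energy, prm$bend_kappa)
  degenerate <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_error(bending(degenerate, prm),
               class = "phagepack_degenerate_geometry")
})

test_that("bending forces sum to zero force and zero torque", {
  set.seed(42)
  for (i in 1:20) {
    tr <- matrix(rnorm(9), 3, 3)
    b <- bending(tr, prm)
    expect_equal(colSums(b$forces), c(0, 0, 0), tolerance = 1e-12)
    torque <- colSums(t(vapply(1:3, function(k) {
      r <- tr[k, ] - tr[2, ]
      f <- b$forces[k, ]
      c(r[2] * f[3] - r[3] * f[2], r[3] * f[1] - r[1] * f[3],
        r[1] * f[2] - r[2] * f[1])
    }, numeric(3))))
    expect_equal(torque, c(0, 0, 0), tolerance = 1e-10)
  }
})

test_that("screened electrostatics truncate, scale linearly in T*, and match closed form", {
  expect_equal(electrostatic(prmQ$elec_cutoff + 0.1, 1, prmQ)$energy, 0)
  e1 <- electrostatic(1.2, 1.0, prmQ)
  e2 <- electrostatic(1.2, 2.0, prmQ)
  expect_equal(e2$energy, 2 * e1$energy)
  expect_equal(e2$force, 2 * e1$force)
  lam <- prmQ$debye_length
  expect_equal(electrostatic(lam, 1, prmQ)$energy,
               prmQ$charge_prefactor * exp(-1) / lam)
  expect_error(electrostatic(0, 1, prmQ), class = "phagepack_singularity")
  expect_error(electrostatic(1, 1, prm), class = "phagepack_invalid_value")
})

test_that("every scalar force is minus the finite-difference energy slope", {
  set.seed(7)
  rs <- runif(100, 0.85, 1.45)
  for (r in rs[1:25]) {
    expect_equal(fene_bond(r, prm)$force,
                 -fd_gradient(function(x) fene_bond(x, prm)$energy, r),
                 tolerance = 1e-6)
  }
  for (r in runif(25, 0.85, 1.11)) {
    expect_equal(excluded_volume(r, prm)$force,
                 -fd_gradient(function(x) excluded_volume(x, prm)$energy, r),
                 tolerance = 1e-6)
  }
  for (r in runif(25, 0.8, 2.8)) {
    expect_equal(electrostatic(r, 1.2, prmQ)$force,
                 -fd_gradient(function(x) electrostatic(x, 1.2, prmQ)$energy, r),
                 tolerance = 1e-6)
  }
  for (i in 1:25) {
    tr <- matrix(rnorm(9), 3, 3)
    b <- bending(tr, prm)
    g <- -matrix(fd_gradient(function(v)
      bending(matrix(v, 3, 3), prm)$energy, as.vector(tr)), 3, 3)
    expect_equal(b$forces, g, tolerance = 1e-5)
  }
})

test_that("total_forces agrees with finite differences of its own energy", {
  pos <- random_chain(8, seed = 11)
  for (setup in list(
    list(p = prm, a = NULL),
    list(p = prmQ, a = NULL),
    list(p = prmQ, a = capsid_assembly(tail = TRUE))
  )) {
    tf <- total_forces(pos, setup$p, setup$a, motor_on = FALSE,
                       reduced_temperature = 1.1)
    g <- -matrix(fd_gradient(function(v)
      total_forces(matrix(v, ncol = 3), setup$p, setup$a,
                   reduced_temperature = 1.1)$energy,
      as.vector(pos)), ncol = 3)
    expect_equal(tf$forces, g, tolerance = 1e-5)
  }
})

test_that("total_forces matches the R-level superposition of scalar terms", {
  pos <- random_chain(7, seed = 3) + matrix(rep(c(0, 0, 1.5), each = 7), 7, 3)
  for (p in list(prm, prmQ)) {
    cpp_U <- total_forces(pos, p, capsid_assembly(tail = TRUE),
                          reduced_temperature = 1.2)$energy
    r_U <- r_reference_energy(pos, p, capsid_assembly(tail = TRUE),
                              reduced_temperature = 1.2)
    expect_equal(cpp_U, r_U, tolerance = 1e-10)
  }
})

test_that("no interactions in range means no forces", {
  p0 <- interaction_params(fene_k = 0, bend_kappa = 0)
  pos <- rbind(c(0, 0, 0), c(4, 0, 0))  # beyond every cutoff
  tf <- total_forces(pos, p0)
  expect_equal(max(abs(tf$forces)), 0)
  expect_equal(tf$energy, 0)
})

test_that("charged minus neutral is exactly the electrostatic term", {
  pos <- random_chain(9, seed = 5)
  fn <- total_forces(pos, prm)
  fq <- total_forces(pos, prmQ)
  elec_U <- 0
  for (i in 1:7) for (j in (i + 2):9) {
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    elec_U <- elec_U + electrostatic(r, 1, prmQ)$energy
  }
  expect_equal(fq$energy - fn$energy, elec_U, tolerance = 1e-10)
})

test_that("internal forces conserve linear momentum", {
  for (seed in 1:5) {
    pos <- random_chain(25, seed = seed)
    tf <- total_forces(pos, prmQ)
    expect_lt(max(abs(colSums(tf$forces))), 1e-10)
  }
})

test_that("flexible neutral chain equilibrates to the 0.97 sigma bond length", {
  p0 <- interaction_params(bend_kappa = 0)
  conf <- sample_free_chain(30, p0, 1.0, n_conformations = 200, stride = 400,
                            n_equil = 5000, seed = 99)
  bl <- apply(conf, 3, function(m)
    mean(sqrt(rowSums((m[-1, ] - m[-nrow(m), ])^2))))
  expect_equal(mean(bl), 0.97, tolerance = 0.01)
})
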