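test_that("event-time distribution handles completions, hand lists and timeouts", {
  mk <- function(ev, id, budget = 100) {
    r <- constant_record(5, id = id, max_steps = budget)
    if (!is.na(ev)) { r$event_time <- ev; r$status <- "completed" }
    r
  }
  single <- event_time_distribution(list(mk(42, 1)))
  expect_equal(single$mean_completed, 42)
  expect_equal(sum(single$histogram$counts), 1)
  expect_equal(single$timeout_count, 0)

  trio <- event_time_distribution(list(mk(10, 1), mk(20, 2), mk(30, 3)))
  expect_equal(trio$mean_completed, 20)
  expect_equal(trio$median_completed, 20)

  all_to <- event_time_distribution(list(mk(NA, 1), mk(NA, 2)))
  expect_equal(all_to$timeout_count, 2)
  expect_true(is.na(all_to$mean_completed))
  expect_equal(all_to$mean_censored, 100)
  expect_equal(sum(all_to$histogram$counts), 0)

  expect_error(event_time_distribution(list()),
               class = "phagepack_invalid_value")
})

test_that("rigid rod conformations flag a non-decaying correlation", {
  rod <- array(0, dim = c(30, 3, 50))
  for (m in 1:50) rod[, 3, m] <- (0:29) * 0.97
  est <- persistence_length_estimate(rod, n_boot = 5)
  expect_equal(est$flag, "non_decaying")
  expect_true(is.infinite(est$lp))
})

test_that("a fully flexible chain has persistence length of order one bead", {
  p0 <- interaction_params(bend_kappa = 0)
  conf <- sample_free_chain(40, p0, 1.0, n_conformations = 150, stride = 500,
                            n_equil = 5000, seed = 8, n_replicas = 10)
  est <- persistence_length_estimate(conf, fit_window = 1:6, n_boot = 20)
  expect_lt(est$lp, 3)
})

test_that("ideal-chain joint statistics match the analytic Boltzmann average", {
  # bonds + bending only: each joint is independent with weight
  # exp(-kappa (1 - cos)/T); <cos> = coth(k) - 1/k
  # without the repulsive core the FENE bond can shrink toward zero where
  # the bending gradient is steep, so this check runs at a smaller time step
  kappa <- 5
  p <- interaction_params(bend_kappa = kappa, lj_epsilon = 0)
  conf <- sample_free_chain(40, p, 1.0, n_conformations = 200, stride = 1000,
                            n_equil = 5000, seed = 10, n_replicas = 20,
                            dt = 0.0025)
  cosbar <- mean(apply(conf, 3, function(m) {
    bv <- diff(m)
    u <- bv / sqrt(rowSums(bv^2))
    mean(rowSums(u[-nrow(u), ] * u[-1, ]))
  }))
  expect_equal(cosbar, ideal_chain_mean_cos(kappa, 1.0), tolerance = 0.02)
})

test_that("calibration brackets with the worm-like-chain initializer and converges", {
  # scaled-down: short chain, loose tolerance - checks the search machinery
  cal <- calibrate_bending_rigidity(target_lp = 5, tolerance = 0.75,
                                    n_beads = 40, n_conformations = 160,
                                    stride = 1000, n_equil = 5000,
                                    n_replicas = 16, seed = 3)
  expect_lt(abs(cal$achieved_lp - 5), 0.75 + 1e-9)
  wlc_guess <- 5 / 0.97
  expect_lt(abs(cal$kappa - wlc_guess) / wlc_guess, 1.0)
  expect_error(calibrate_bending_rigidity(target_lp = 0.5),
               class = "phagepack_invalid_value")
})

test_that("packing fraction follows the closed form", {
  expect_equal(packing_fraction(0), 0)
  expect_equal(packing_fraction(1, 1, 0.5), 1)
  expect_equal(packing_fraction(100, 1, 3.02),
               100 * (pi / 6) / ((4 / 3) * pi * 3.02^3))
  expect_equal(round(packing_fraction(100, 1, 3.02), 3), 0.454)
})

test_that("nematic order metric matches hand-computed limits", {
  asm <- capsid_assembly()
  # all interior bonds parallel (z): order 1
  z <- cbind(0, 0, seq(-1.4, 1.4, by = 0.35))
  expect_equal(as.numeric(intracapsid_order_metric(z, asm)), 1,
               tolerance = 1e-9)
  # two equal populations along x and y: Q = diag(1/4, 1/4, -1/2)
  zig <- matrix(0, 11, 3)
  for (i in 2:11) {
    step <- if (i %% 2 == 0) c(0.35, 0, 0) else c(0, 0.35, 0)
    zig[i, ] <- zig[i - 1, ] + step
  }
  zig <- sweep(zig, 2, colMeans(zig))
  expect_equal(as.numeric(intracapsid_order_metric(zig, asm)), 0.25,
               tolerance = 1e-9)
  # isotropic directions approach zero order
  set.seed(42)
  n <- 1001
  dirs <- matrix(rnorm(3 * n), n, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  walk <- apply(rbind(0, dirs * 0.001), 2, cumsum)
  expect_lt(as.numeric(intracapsid_order_metric(walk, asm)), 0.1)
  # fewer than 2 interior bonds is an error
  expect_error(intracapsid_order_metric(cbind(10, 10, 10:12), asm),
               class = "phagepack_invalid_value")
})
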