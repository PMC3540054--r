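cfg0 <- test_config()
asm0 <- phagepack:::assembly_from_config(cfg0)

test_that("packing initial state has one bead inside and sane bonds", {
  st <- build_initial_packing_state(cfg0, seed = 11)
  expect_equal(unname(count_occupancy(st, asm0)), c(1L, 0L))
  bl <- sqrt(rowSums((st$pos[-1, ] - st$pos[-cfg0$n_beads, ])^2))
  expect_true(all(bl > 0.8 & bl < 1.2))
  # clash-free
  d <- as.matrix(dist(st$pos))
  diag(d) <- Inf
  expect_gt(min(d), 0.9 - 1e-9)
  # seeding contract: same first bead, different outside coil
  st2 <- build_initial_packing_state(cfg0, seed = 12)
  expect_equal(st$pos[1, ], st2$pos[1, ])
  expect_false(isTRUE(all.equal(st$pos[cfg0$n_beads, ],
                                st2$pos[cfg0$n_beads, ])))
})

test_that("with a tail the initial chain threads the tail single-file", {
  cfgT <- test_config(tail_present = TRUE)
  asmT <- phagepack:::assembly_from_config(cfgT)
  st <- build_initial_packing_state(cfgT, seed = 4)
  occ <- count_occupancy(st, asmT)
  expect_equal(unname(occ["inside"]), 1L)
  expect_gt(unname(occ["tail"]), 3L)  # beads strung through the 6-sigma tail
  rho <- sqrt(st$pos[, 1]^2 + st$pos[, 2]^2)
  in_tail <- classify_position(st$pos, asmT) == "in_tail"
  expect_true(all(rho[in_tail] < 0.21))
})

test_that("equilibration pins the anchor and leaves it in place", {
  st <- build_initial_packing_state(cfg0, seed = 21)
  p0 <- st$pos[1, ]
  st2 <- equilibrate(st, cfg0, anchor = 1, seed = 21)
  expect_equal(st2$pos[1, ], p0, tolerance = 1e-12)
  expect_equal(st2$step, cfg0$equilibration_steps)
  # the anchored bead is still the one inside
  expect_equal(classify_position(st2$pos[1, ], asm0), "inside_capsid")
})

test_that("zero motor force produces no packing progress (timeout)", {
  cfg <- test_config(motor_force = 0, max_steps = 6000,
                     equilibration_steps = 1000, sampling_stride = 2000)
  st <- build_initial_packing_state(cfg, seed = 31)
  st <- equilibrate(st, cfg, anchor = 1, seed = 31)
  rec <- run_packing(st, cfg, seed = 31)
  expect_equal(rec$status, "timeout")
  expect_true(is.na(rec$event_time))
  expect_lt(max(rec$timeseries$beads_inside), 5)
})

test_that("a completed packing run ends with every bead inside", {
  cfg <- test_config(max_steps = 1e5, equilibration_steps = 1000,
                     sampling_stride = 1000)
  st <- build_initial_packing_state(cfg, seed = 41)
  st <- equilibrate(st, cfg, anchor = 1, seed = 41)
  rec <- run_packing(st, cfg, seed = 41)
  expect_equal(rec$status, "completed")
  final <- attr(rec, "state")
  expect_true(all(sqrt(rowSums(final$pos^2)) <
                    cfg$geometry$capsid_radius))
  # the last sample counts beads in the capsid proper; at most one bead can
  # still sit in the pore channel inside the sphere at the event step
  expect_gte(tail(rec$timeseries$beads_inside, 1), cfg$n_beads - 1L)
  # timeseries steps are monotone
  expect_true(all(diff(rec$timeseries$step) > 0))
})

test_that("constructed packed state is clash-free with bead N at the pore pole", {
  st <- build_packed_state(cfg0, seed = 7)
  r <- sqrt(rowSums(st$pos^2))
  expect_true(all(r < cfg0$geometry$capsid_radius))
  d <- as.matrix(dist(st$pos))
  diag(d) <- Inf
  expect_gt(min(d), 0.9)
  bl <- sqrt(rowSums(diff(st$pos)^2))
  expect_true(all(bl < cfg0$interaction$fene_r0))
  # bead N (last packed) sits closest to the pore on the +z axis
  expect_equal(which.max(st$pos[, 3]), cfg0$n_beads)
})

test_that("tailless ejection initial state leaves exactly one bead outside", {
  st <- build_initial_ejection_state(cfg0, seed = 7)
  occ <- count_occupancy(st, asm0)
  expect_equal(unname(occ), c(cfg0$n_beads - 1L, 0L))
  bl <- sqrt(rowSums(diff(st$pos)^2))
  expect_true(all(bl < cfg0$interaction$fene_r0))
  expect_equal(classify_position(st$pos[cfg0$n_beads, ], asm0), "outside")
})

test_that("tailed ejection initial state starts the end in the tube lumen", {
  cfgT <- test_config(tail_present = TRUE)
  asmT <- phagepack:::assembly_from_config(cfgT)
  st <- build_initial_ejection_state(cfgT, seed = 7)
  N <- cfgT$n_beads
  # terminal bead just past the capsid wall, inside the tube, on axis
  expect_equal(classify_position(st$pos[N, ], asmT), "in_tail")
  expect_lt(sqrt(sum(st$pos[N, 1:2]^2)), asmT$tail_radius)
  occ <- count_occupancy(st, asmT)
  expect_equal(unname(occ), c(N - 1L, 1L))
  bl <- sqrt(rowSums(diff(st$pos)^2))
  expect_true(all(bl < cfgT$interaction$fene_r0))
})

test_that("a completed ejection ends with an empty capsid and tail", {
  cfg <- test_config(n_beads = 10L, max_steps = 4e5,
                     equilibration_steps = 1000, sampling_stride = 5000)
  asm <- phagepack:::assembly_from_config(cfg)
  st <- build_initial_ejection_state(cfg, seed = 3)
  st <- equilibrate(st, cfg, anchor = 10, seed = 3)
  rec <- run_ejection(st, cfg, seed = 3)
  expect_equal(rec$status, "completed")
  occ <- count_occupancy(attr(rec, "state"), asm)
  expect_equal(unname(occ), c(0L, 0L))
})

test_that("ensemble aggregation reproduces the hand-computed mean and SEM", {
  recs <- list(constant_record(10, id = 1), constant_record(20, id = 2))
  ens <- aggregate_ensemble(recs, test_config(n_beads = 40L), "packing")
  expect_true(all(ens$grid$mean == 15))
  expect_true(all(abs(ens$grid$sem - 5) < 1e-12))
  expect_equal(ens$completion_fraction, 0)
  # single replicate: mean is the curve, SEM is zero-width
  ens1 <- aggregate_ensemble(recs[1], test_config(n_beads = 40L), "packing")
  expect_true(all(ens1$grid$mean == 10))
  expect_true(all(ens1$grid$sem == 0))
})

test_that("ensembles are reproducible from the master seed", {
  cfg <- test_config(n_beads = 8L, max_steps = 8000,
                     equilibration_steps = 1000, sampling_stride = 2000,
                     n_replicates = 2L)
  a <- run_ensemble(cfg, "packing", seed = 99)
  b <- run_ensemble(cfg, "packing", seed = 99)
  expect_identical(a$grid, b$grid)
  expect_identical(a$event_times, b$event_times)
})

test_that("ensemble packing curves are non-decreasing in time", {
  cfg <- test_config(n_beads = 12L, max_steps = 6e4,
                     equilibration_steps = 1000, sampling_stride = 250,
                     n_replicates = 3L)
  ens <- run_ensemble(cfg, "packing", seed = 5)
  # ensemble-mean monotonicity, allowing tiny thermal re-exit wiggles
  expect_gt(nrow(ens$grid), 2)
  expect_true(all(diff(ens$grid$mean) > -1.5))
  expect_gt(tail(ens$grid$mean, 1), ens$grid$mean[1])
})
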