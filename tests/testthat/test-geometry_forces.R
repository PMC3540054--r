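asm0 <- capsid_assembly()
asmT <- capsid_assembly(tail = TRUE)
R <- asm0$capsid_radius

test_that("position classification partitions space as documented", {
  expect_equal(classify_position(c(0, 0, 0), asm0), "inside_capsid")
  expect_equal(classify_position(c(0, 0, 10), asm0), "outside")
  expect_equal(classify_position(c(0, 0, R + 3), asmT), "in_tail")
  expect_equal(classify_position(c(0, 0, R + 3), asm0), "outside")
  expect_equal(classify_position(c(0, 0, R), asm0), "in_pore")
  # matrix input classifies rowwise
  m <- rbind(c(0, 0, 0), c(2, 2, 2), c(0.2, 0, R))
  expect_equal(classify_position(m, asm0),
               c("inside_capsid", "outside", "in_pore"))
})

test_that("wall force is a linear two-sided repulsion with pore exclusion", {
  expect_equal(as.numeric(wall_force(c(0, 0, 0), asm0)), c(0, 0, 0))
  # inside the shell, halfway in: inward force of magnitude k * range/2
  p <- c(R - asm0$wall_range / 2, 0, 0)
  f <- wall_force(p, asm0)
  expect_equal(as.numeric(f),
               c(-asm0$wall_stiffness * asm0$wall_range / 2, 0, 0))
  # outside the shell, halfway out: outward force of the same magnitude
  q <- c(0, R + asm0$wall_range / 2, 0)
  fq <- wall_force(q, asm0)
  expect_equal(as.numeric(fq),
               c(0, asm0$wall_stiffness * asm0$wall_range / 2, 0))
  # bead centred in the pore opening feels no wall force
  expect_equal(as.numeric(wall_force(c(0, 0, R), asm0)), c(0, 0, 0))
})

test_that("tail retention force pulls protruding beads back into the lumen", {
  mid <- c(0, 0, R + 3)
  expect_equal(as.numeric(tail_retention_force(mid, asmT)), c(0, 0, 0))
  # in the lumen up to tail_radius: still free
  expect_equal(as.numeric(tail_retention_force(c(0.69, 0, R + 3), asmT)),
               c(0, 0, 0))
  # half a bead into the sheath: magnitude stiffness * sigma/2, toward axis
  p <- c(asmT$tail_radius + 0.5, 0, R + 3)
  f <- tail_retention_force(p, asmT)
  expect_equal(as.numeric(f), c(-asmT$tail_stiffness * 0.5, 0, 0))
  # linear in the excess below saturation
  f2 <- tail_retention_force(c(asmT$tail_radius + 0.2, 0, R + 3), asmT)
  expect_equal(as.numeric(f2)[1], -asmT$tail_stiffness * 0.2)
  # outer side of the sheath: pushed off the tube, not captured
  f3 <- tail_retention_force(c(asmT$tail_radius + 1.8, 0, R + 3), asmT)
  expect_gt(as.numeric(f3)[1], 0)
  # beyond the sheath or the tail tip: no force
  expect_equal(as.numeric(tail_retention_force(c(asmT$tail_radius + 2.1, 0, R + 3),
                                               asmT)), c(0, 0, 0))
  tip <- c(asmT$tail_radius, 0, R + asmT$tail_length + 1)
  expect_equal(as.numeric(tail_retention_force(tip, asmT)), c(0, 0, 0))
  expect_error(tail_retention_force(p, asm0), class = "phagepack_invalid_value")
})

test_that("motor force is 80 units toward the center inside the capture region", {
  pore <- c(0, 0, R)
  expect_equal(motor_force(pore, asm0, motor_on = FALSE), c(0, 0, 0))
  f <- motor_force(pore + c(0, 0, 1e-6), asm0, motor_on = TRUE)
  expect_equal(sqrt(sum(f^2)), 80, tolerance = 1e-9)
  expect_equal(f / sqrt(sum(f^2)), c(0, 0, -1), tolerance = 1e-6)
  far <- c(0, 0, R + asm0$motor_capture_radius + 5)
  expect_equal(motor_force(far, asm0, motor_on = TRUE), c(0, 0, 0))
})

test_that("occupancy counts follow the classification", {
  pos_full <- matrix(rnorm(3 * 30, sd = 0.5), 30, 3)
  pos_full <- pos_full / pmax(1, sqrt(rowSums(pos_full^2)) / 2.0)
  expect_equal(unname(count_occupancy(pos_full, asm0)[1]), 30L)
  pos_out <- cbind(0, 0, seq(R + asmT$tail_length + 10, by = 1,
                             length.out = 5))
  expect_equal(unname(count_occupancy(pos_out, asmT)), c(0L, 0L))
  toy <- rbind(c(0, 0, 0), c(0, 0, R + 3), c(8, 0, 0))
  expect_equal(unname(count_occupancy(toy, asmT)), c(1L, 1L))
})

test_that("the wall shell cannot be crossed at thermal speed", {
  # launch a bead straight at the wall at the T* = 1.2 thermal speed and
  # integrate; it must turn back before penetrating 0.5 sigma past the shell
  v_th <- sqrt(3 * 1.2)
  st <- system_state(matrix(c(R - asm0$wall_range, 0, 0), 1, 3),
                     matrix(c(v_th, 0, 0), 1, 3))
  p <- interaction_params(bend_kappa = 0)
  st2 <- velocity_verlet_step(st, p, asm0, dt = 0.005, n_steps = 400)
  expect_lt(max(abs(st2$pos[1, 1])), R + 0.5)
  expect_lt(st2$pos[1, 1], R - asm0$wall_range)  # reflected back inside
})
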