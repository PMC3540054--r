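test_that("reduced-to-physical conversions reproduce the stated anchors", {
  expect_equal(as.numeric(to_physical(80, "force")), 128)
  expect_equal(as.numeric(to_physical(1, "force")), 1.6)
  expect_equal(round(as.numeric(to_physical(0.75, "length")), 1), 1.9)
  expect_equal(as.numeric(to_physical(1, "temperature")), 37)
  # energy unit is k_B T at 37 C, within 1% of 4.3 pN nm
  expect_lt(abs(as.numeric(to_physical(1, "energy")) - 4.3) / 4.3, 0.01)
})

test_that("physical round trip is the identity for every kind", {
  u <- unit_system()
  for (kind in c("force", "length", "energy", "temperature")) {
    x <- c(0.1, 1, 7.5, 80)
    expect_equal(from_physical(as.numeric(to_physical(x, kind, u)), kind, u),
                 x, tolerance = 1e-12)
  }
})

test_that("Bjerrum length at 37 C in water is about 0.7 nm", {
  lb <- bjerrum_length_nm(310.15, 80)
  expect_equal(round(lb, 1), 0.7)
  # scales inversely with temperature and permittivity
  expect_gt(bjerrum_length_nm(280, 80), lb)
  expect_lt(bjerrum_length_nm(310.15, 100), lb)
})

test_that("empty config gives the documented defaults", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines("", f)
  cfg <- load_config(f)
  expect_equal(cfg$reduced_temperature, 1.0)
  expect_equal(cfg$n_beads, 100L)
  expect_false(cfg$charged)
  expect_false(cfg$tail_present)
  expect_true(cfg$hydrodynamics)
  expect_equal(cfg$motor_force, 80)
})

test_that("config validation raises distinct named errors", {
  expect_error(sim_config(reduced_temperature = -1),
               class = "phagepack_invalid_value")
  expect_error(sim_config(motor_force = -5),
               class = "phagepack_invalid_value")
  expect_error(sim_config(nonsense_key = 1),
               class = "phagepack_unknown_key")
  expect_error(sim_config(interaction = list(elec_cutoff = 0.5)),
               class = "phagepack_invalid_value")
  expect_error(load_config(file.path(tempdir(), "does_not_exist.yml")),
               class = "phagepack_missing_file")
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines("reduced_temperature: -2", f)
  expect_error(load_config(f), class = "phagepack_invalid_value")
})

test_that("tail flag populates the 6 x 0.7 sigma tail geometry", {
  f <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("tail_present: yes", "n_beads: 40"), f)
  cfg <- load_config(f)
  expect_true(cfg$tail_present)
  expect_equal(cfg$geometry$tail_length, 6)
  expect_equal(cfg$geometry$tail_radius, 0.7)
  asm <- phagepack:::assembly_from_config(cfg)
  expect_true(asm$tail)
})
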