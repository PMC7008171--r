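test_that("the beagle/risperidone fixture matches the published inputs", {
  p <- fixture()
  printed <- list(
    c("drug", "mol_weight", 410.49),
    c("drug", "log_p", 3.04),
    c("drug", "blood_plasma_ratio", 0.506),
    c("drug", "fu_plasma", 0.083),
    c("drug", "ref_solubility", 0.9),
    c("drug", "ref_solubility_ph", 6.8),
    c("drug", "diffusion_coeff", 0.64e-5),
    c("drug", "precipitation_time", 900),
    c("drug", "particle_density", 1.2),
    c("drug", "particle_radius", 25),
    c("absorption", "peff", 5.3894e-4),
    c("absorption", "fu_oral_tissue", 0.15382),
    c("absorption", "mucosa_diffusivity", 9.383e-7),
    c("disposition", "first_pass_extraction", 0.51),
    c("disposition", "vc", 0.3139),
    c("disposition", "cl", 0.5903),
    c("disposition", "k12", 16.352),
    c("disposition", "k21", 9.007),
    c("disposition", "k13", 0.4625),
    c("disposition", "k31", 0.4103),
    c("disposition", "v2", 0.56988),
    c("disposition", "v3", 0.35383),
    c("design", "dose", 1),
    c("design", "body_weight", 9.0425)
  )
  for (row in printed) {
    expect_equal(p[[row[1]]][[row[2]]], as.numeric(row[3]),
                 info = paste(row[1], row[2]))
  }
  expect_identical(p$drug$compound_type, "diprotic_base")
  expect_equal(p$drug$pka_values, c(8.24, 3.11))
  expect_equal(p$design$sampling_times,
               c(0.167, 0.333, 0.5, 0.75, 1.0, 1.5, 2.0, 3.0, 4.0,
                 6.0, 8.0, 12, 24, 32))
  # total clearance, arithmetic on the per-kg entry
  expect_equal(p$disposition$cl * p$design$body_weight, 5.3378,
               tolerance = 1e-4)
  # micro-constant self-consistency: k12*Vc ~ k21*V2, k13*Vc ~ k31*V3
  expect_equal(p$disposition$k12 * p$disposition$vc,
               p$disposition$k21 * p$disposition$v2, tolerance = 1e-4)
  expect_equal(p$disposition$k13 * p$disposition$vc,
               p$disposition$k31 * p$disposition$v3, tolerance = 1e-4)
  expect_equal(nrow(validate_parameters(p)), 0L)
})

test_that("validate_parameters reports violated invariants by field", {
  p <- fixture()
  p$drug$fu_plasma <- 1.5
  iss <- validate_parameters(p)
  expect_equal(nrow(iss), 1L)
  expect_match(iss$field, "fu_plasma")

  p <- fixture()
  p$drug$pka_values <- c(3.11, 8.24)
  iss <- validate_parameters(p)
  expect_match(iss$field, "pka_values")
  expect_match(iss$rule, "decreasing")

  p <- fixture()
  p$design$dose <- -1
  p$design$sampling_times <- c(2, 1)
  iss <- validate_parameters(p)
  expect_setequal(iss$field, c("design$dose", "design$sampling_times"))
})

test_that("config serialization round-trips the fixture field-for-field", {
  p <- fixture()
  path <- withr::local_tempfile(fileext = ".json")
  write_config(p, path)
  q <- load_config(path)
  expect_equal(unclass(q$drug), unclass(p$drug))
  expect_equal(unclass(q$absorption), unclass(p$absorption))
  expect_equal(unclass(q$disposition), unclass(p$disposition))
  expect_equal(unclass(q$design), unclass(p$design))
})

test_that("config loading applies defaults, validates, and names bad keys", {
  # omitted optional key falls back to the fixture default
  q <- load_config('{"drug": {"log_p": 3.1}, "design": {"dose": 2}}')
  expect_equal(q$drug$particle_radius, 25)
  expect_equal(q$drug$log_p, 3.1)
  expect_equal(q$design$dose, 2)

  expect_error(load_config('{"design": {"dose": -1}}'), "dose")
  expect_error(load_config('{"drg": {}}'), "unknown config block")
  expect_error(load_config('{"drug": {"mw": 1}}'), "unknown key")
  expect_error(load_config("not json {"), "parse")
})

test_that("published validation table carries the reported endpoint values", {
  ref <- reference_validation()
  expect_equal(ref$predicted, c(0.53, 38.43, 91.56))
  expect_equal(ref$observed, c(0.62, 59.38, 101.87))
  oral <- reference_oral_fractions()
  expect_equal(oral$fraction, c(0.070, 0.114, 0.195))
})
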