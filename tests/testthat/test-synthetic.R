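test_that("synthetic studies are bitwise reproducible under a fixed seed", {
  p <- fixture()
  nm <- noise_model(seed = 99)
  s1 <- cached("study99",
               generate_plasma_study(p, test_scales(), n_subjects = 2,
                                     noise = nm, routes = c("iv", "ig")))
  s2 <- generate_plasma_study(p, test_scales(), n_subjects = 2,
                              noise = nm, routes = c("iv", "ig"))
  expect_identical(s1$curves, s2$curves)
  s3 <- generate_plasma_study(p, test_scales(), n_subjects = 2,
                              noise = noise_model(seed = 100),
                              routes = c("iv", "ig"))
  expect_false(identical(s1$curves, s3$curves))
})

test_that("noise-free curves equal the engine output at the grid", {
  p <- fixture()
  study <- generate_plasma_study(p, test_scales(), n_subjects = 1,
                                 noise = noise_model(0, 0, seed = 1,
                                                     lloq = 0),
                                 routes = "iv")
  clean <- study$truth$simulations[["iv shared"]]
  grid <- p$design$sampling_times
  expected <- stats::approx(clean$curve$time_h, clean$curve$conc_ug_L,
                            xout = grid)$y
  expect_equal(study$curves$conc_ug_L, expected, tolerance = 1e-9)
})

test_that("no emitted concentration lies between zero and the LLOQ", {
  study <- cached("study99",
                  generate_plasma_study(fixture(), test_scales(),
                                        n_subjects = 2,
                                        noise = noise_model(seed = 99),
                                        routes = c("iv", "ig")))
  conc <- study$curves$conc_ug_L
  measured <- conc[!is.na(conc)]
  expect_true(all(measured == 0 | measured >= study$noise$lloq))
})

test_that("the residual-error model has the nominal CV and is unbiased", {
  nm <- noise_model(proportional_cv = 0.10, additive_sd = 0.1, lloq = 0)
  set.seed(2024)
  reps <- replicate(200, odfpbpk:::apply_noise(100, nm, censor = FALSE))
  cv <- stats::sd(reps) / mean(reps)
  expect_gt(cv, 0.08)
  expect_lt(cv, 0.12)
  set.seed(2025)
  big <- replicate(1e4, odfpbpk:::apply_noise(100, nm, censor = FALSE))
  expect_lt(abs(mean(big) / 100 - 1), 0.01)
})

test_that("dissolution profiles cover the four compendial media and stay
           monotone without noise", {
  media <- default_dissolution_media()
  expect_equal(nrow(media), 4L)
  expect_true(any(grepl("HCl", media$label)))
  expect_true(any(grepl("acetate", media$label)))
  expect_true(any(grepl("phosphate", media$label)))
  expect_true(any(grepl("water", media$label)))
  profs <- generate_dissolution_profiles(default_film_z(),
                                         noise = noise_model(0, 0, seed = 3))
  expect_length(profs, 4L)
  for (pr in profs) {
    expect_true(all(diff(pr$dissolved_fraction) >= -1e-12))
    expect_gte(pr$dissolved_fraction[pr$time_min == 2], 0.95)
  }
})

test_that("noiseless end-to-end recovery is essentially exact", {
  rep0 <- cached("recovery_clean",
                 recovery_suite(seed = 7, n_replicates = 2,
                                noise = noise_model(0, 0)))
  sm <- rep0$summary
  expect_lt(abs(sm$median_bias[sm$quantity == "z"]), 0.01)
  expect_lt(abs(sm$median_bias[sm$quantity == "cl"]), 0.01)
  expect_lt(abs(sm$median_bias[sm$quantity == "vc"]), 0.01)
  # NCA AUC carries the sampling-grid head bias (distribution phase faster
  # than the first sample); bounded, not zero
  expect_lt(abs(sm$median_bias[sm$quantity == "auc"]), 0.05)
  expect_identical(tidy(rep0), rep0$replicates)
  expect_identical(glance(rep0), rep0$summary)
})

test_that("recovery reports are reproducible for identical seeds", {
  r1 <- recovery_suite(seed = 5, n_replicates = 2)
  r2 <- recovery_suite(seed = 5, n_replicates = 2)
  expect_identical(r1$replicates, r2$replicates)
})
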