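test_that("i.v. route reduces to pure disposition with the AUC identity", {
  sim <- cached_route_sim("iv")
  s <- summarize_exposure(sim)
  expect_equal(s$tmax, sim$curve$time_h[1])
  expect_equal(s$cmax, 1000 / (0.3139 * 9.0425), tolerance = 1e-4)
  expect_equal(s$auc_inf, 1000 / (0.5903 * 9.0425), tolerance = 0.005)
  expect_equal(s$bioavailability, 100)
  expect_equal(sim$oral_fraction, 0)
  ledger <- mass_balance_report(sim)$ledger
  nonzero <- ledger$item[ledger$amount_ug > 1e-6]
  expect_true(all(nonzero %in% c("central", "peripheral_2", "peripheral_3",
                                 "eliminated")))
})

test_that("every route conserves mass to 1e-6 relative", {
  for (route in c("iv", "ig", "supralingual", "sublingual")) {
    sim <- cached_route_sim(route)
    expect_lt(sim$max_balance_error, 1e-6)
    expect_lt(mass_balance_report(sim)$max_relative_error, 1e-6)
  }
})

test_that("fractions and the ledger partition the dose coherently", {
  sim <- cached_route_sim("supralingual")
  expect_gt(sim$oral_fraction, 0)
  expect_lt(sim$oral_fraction, 1)
  expect_gt(sim$gut_fraction_absorbed, 0.9)  # high-permeability compound
  reg <- sim$regional_fractions
  expect_equal(sum(reg$fraction[reg$region == "oral"]), sim$oral_fraction,
               tolerance = 1e-9)
  swallowed <- utils::tail(sim$trajectory$swallowed_cum, 1) / 1000
  expect_equal(sum(reg$fraction[reg$region == "gut"]),
               sim$gut_fraction_absorbed * swallowed, tolerance = 1e-9)
})

test_that("supralingual and sublingual exposure agree within 15%", {
  a <- summarize_exposure(cached_route_sim("supralingual"))$auc_inf
  b <- summarize_exposure(cached_route_sim("sublingual"))$auc_inf
  expect_lt(abs(a - b) / a, 0.15)
})

test_that("exposure is linear in dose", {
  p2 <- fixture()
  p2$design$dose <- 2
  for (route in c("iv", "ig")) {
    s1 <- summarize_exposure(cached_route_sim(route))
    sim2 <- simulate_route(p2, route, scales = test_scales(),
                           times = peak_grid())
    s2 <- summarize_exposure(sim2)
    expect_equal(s2$auc_inf, 2 * s1$auc_inf, tolerance = 1e-5)
    expect_equal(s2$cmax, 2 * s1$cmax, tolerance = 1e-5)
  }
})

test_that("a zero hold approaches the solid-film intragastric arm", {
  sup0 <- simulate_route(fixture(), "supralingual", hold_time = 0,
                         scales = test_scales(), times = peak_grid())
  ig_solid <- simulate_route(fixture(), "ig", ig_solid = TRUE,
                             scales = test_scales(), times = peak_grid())
  expect_equal(sup0$curve$conc_ug_L, ig_solid$curve$conc_ug_L,
               tolerance = 1e-8)
})

test_that("the pre-dissolved i.g. arm peaks no later than the solid arm", {
  ig <- summarize_exposure(cached_route_sim("ig"))
  ig_solid <- summarize_exposure(
    simulate_route(fixture(), "ig", ig_solid = TRUE, scales = test_scales(),
                   times = peak_grid()))
  expect_lte(ig$tmax, ig_solid$tmax + 1e-9)
  expect_equal(ig$auc_inf, ig_solid$auc_inf, tolerance = 0.01)
})

test_that("invalid routes are rejected", {
  expect_error(simulate_route(fixture(), "intramuscular"), "invalid route")
})

test_that("summaries and tidiers expose the expected columns", {
  sim <- cached_route_sim("supralingual")
  s <- summarize_exposure(sim)
  expect_named(s, c("tmax", "cmax", "auc_0t", "auc_inf", "bioavailability"))
  expect_gte(s$auc_inf, s$auc_0t)
  td <- tidy(sim)
  expect_true(all(c("time_h", "conc_ug_L", "route") %in% names(td)))
  g <- glance(sim)
  expect_equal(g$route, "supralingual")
  expect_lt(g$max_balance_error, 1e-6)
  expect_s3_class(autoplot(sim), "ggplot")
  expect_s3_class(plot_regional_fractions(sim), "ggplot")
})
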