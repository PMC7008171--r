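test_that("default dog gut has the canonical nine-compartment layout", {
  gut <- default_dog_gut()
  expect_equal(nrow(gut), 9L)
  expect_equal(sum(gut$name == "stomach"), 1L)
  expect_equal(sum(gut$name == "colon"), 1L)
  expect_equal(sum(grepl("^si", gut$name)), 7L)
  expect_equal(sum(gut$transit_h[grepl("^si", gut$name)]), 2.0)
  expect_false(gut$absorbing[gut$name == "stomach"])
  expect_silent(odfpbpk:::validate_gut_table(gut))
  gut3 <- default_dog_gut(si_transit_h = 3)
  expect_equal(sum(gut3$transit_h[grepl("^si", gut3$name)]), 3.0)
})

test_that("absorption rate constant follows ka = 2 Peff / R in 1/h", {
  expect_equal(absorption_rate_constant(5.3894e-4, 0.5),
               2 * 5.3894e-4 / 0.5 * 3600)
  expect_equal(absorption_rate_constant(5.3894e-4, 0.5), 7.76,
               tolerance = 1e-3)
  expect_equal(absorption_rate_constant(0, 0.5), 0)
  expect_equal(absorption_rate_constant(1e-4, 1.0),
               absorption_rate_constant(1e-4, 0.5) / 2)
})

stomach_bolus <- function(amount_ug = 1000, state = "dissolved") {
  tibble::tibble(time_h = 0, compartment = "stomach", state = state,
                 amount_ug = amount_ug)
}

test_that("zero permeability sends the whole dose to feces", {
  p <- fixture()
  p$absorption$peff <- 1e-30
  sim <- simulate_gut(p, input_schedule = stomach_bolus(),
                      times = c(seq(0, 32, by = 0.5), seq(40, 120, by = 4)))
  fa <- fraction_absorbed(sim)
  expect_equal(attr(fa, "total"), 0, tolerance = 1e-12)
  expect_equal(utils::tail(sim$trajectory$fecal_cum, 1), 1000,
               tolerance = 1e-3)
})

test_that("gut ledger conserves mass at every output time", {
  sim <- cached("gut_default_sim",
                simulate_gut(fixture(), input_schedule = stomach_bolus()))
  total <- odfpbpk:::ledger_total(sim$trajectory, sim$context)
  expect_lt(max(abs(total - 1000)) / 1000, 1e-6)
  fa <- fraction_absorbed(sim)
  expect_equal(sum(fa$fraction_absorbed), attr(fa, "total"))
  expect_equal(fa$fraction_absorbed[fa$compartment == "stomach"], 0)
})

test_that("scheduled (timed) luminal inputs are honored", {
  sched <- tibble::tibble(time_h = c(0, 1), compartment = c("stomach", "si1"),
                          state = "dissolved", amount_ug = c(400, 600))
  sim <- simulate_gut(fixture(), input_schedule = sched,
                      times = seq(0, 24, by = 0.25))
  traj <- sim$trajectory
  before <- traj[traj$time_h <= 0.99, ]
  total_before <- odfpbpk:::ledger_total(before, sim$context)
  expect_lt(max(abs(total_before - 400)) / 400, 1e-6)
  total_after <- odfpbpk:::ledger_total(traj[traj$time_h > 1, ], sim$context)
  expect_lt(max(abs(total_after - 1000)) / 1000, 1e-6)
  expect_error(
    simulate_gut(fixture(),
                 input_schedule = tibble::tibble(
                   time_h = 0, compartment = "nowhere",
                   state = "dissolved", amount_ug = 1)))
})

test_that("gut absorption matches the analytic CAT closed form within 2%", {
  # instantaneous dissolution, seven equal-ka SI segments as the only
  # absorbing sites: Fa = 1 - (1 + ka T / 7)^-7
  p <- fixture()
  p$absorption$peff <- 5e-5  # keeps Fa well away from 1
  gut <- default_dog_gut()
  gut$ka_scale[gut$name == "colon"] <- 0
  ka <- absorption_rate_constant(p$absorption$peff, 0.5)
  fa_analytic <- 1 - (1 + ka * 2.0 / 7)^-7
  sched <- tibble::tibble(time_h = 0, compartment = "si1",
                          state = "dissolved", amount_ug = 1000)
  sim <- simulate_gut(p, gut = gut, input_schedule = sched,
                      times = c(seq(0, 32, 0.25), seq(33, 150, 3)))
  expect_equal(attr(fraction_absorbed(sim), "total"), fa_analytic,
               tolerance = 0.02)
})

test_that("fraction absorbed is monotone in permeability and transit time", {
  fa_at <- function(peff_scale = 1, si_transit = 2) {
    p <- fixture()
    p$absorption$peff <- p$absorption$peff * peff_scale
    sim <- simulate_gut(p, gut = default_dog_gut(si_transit),
                        input_schedule = stomach_bolus(),
                        times = seq(0, 48, by = 0.5))
    attr(fraction_absorbed(sim), "total")
  }
  fas <- c(fa_at(0.002), fa_at(0.02), fa_at(0.2))
  expect_true(all(diff(fas) > 0))
  expect_gte(fa_at(0.02, si_transit = 4), fa_at(0.02, si_transit = 2))
})

test_that("gut physiology override CSV round-trips", {
  gut <- default_dog_gut()
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(gut, path, row.names = FALSE)
  back <- read_gut_physiology_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(gut))
  bad <- gut[, -2]
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_gut_physiology_csv(path), "volume_ml")
})
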