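# Shared fixtures; expensive simulations are cached for the whole test run.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

fixture <- function() beagle_risperidone_fixture()

# calibrated scales frozen from calibrate_mucosa_scales(); the calibration
# itself is exercised in the acceptance suite
test_scales <- function() default_mucosa_scales()

# dense early grid so peak metrics are resolved to ~0.01 h
peak_grid <- function(hold = 0) {
  sort(unique(c(default_output_grid(hold_time = hold),
                seq(0.1, 2, by = 0.01), hold / 60)))
}

cached_route_sim <- function(route, hold = 2, fpe_on_mucosal = TRUE) {
  key <- paste("route", route, hold, fpe_on_mucosal)
  cached(key, simulate_route(fixture(), route, hold_time = hold,
                             scales = test_scales(),
                             fpe_on_mucosal = fpe_on_mucosal,
                             times = peak_grid(hold)))
}
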