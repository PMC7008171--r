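#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data :=
NULL

#' Tidy a route simulation into its plasma curve
#'
#' @param x A `pbpk_simulation`.
#' @param ... Unused.
#' @return A tibble with `time_h`, `conc_ug_L`, `route`.
#' @method tidy pbpk_simulation
#' @export
tidy.pbpk_simulation <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x$curve), route = x$route)
}

#' One-row summary of a route simulation
#'
#' @param x A `pbpk_simulation`.
#' @param ... Unused.
#' @return Exposure metrics plus absorption fractions and the mass-balance
#'   error.
#' @method glance pbpk_simulation
#' @export
glance.pbpk_simulation <- function(x, ...) {
  dplyr::mutate(summarize_exposure(x),
                oral_fraction = x$oral_fraction,
                gut_fraction_absorbed = x$gut_fraction_absorbed,
                systemic_fraction = x$systemic_fraction,
                max_balance_error = x$max_balance_error,
                route = x$route, hold_time_min = x$hold_time)
}

#' Tidy a sensitivity scan into long format
#'
#' @param x A `sensitivity_result`.
#' @param ... Unused.
#' @return A tibble with `parameter`, grid `value`, `metric`, `output`.
#' @method tidy sensitivity_result
#' @export
tidy.sensitivity_result <- function(x, ...) {
  tidyr::pivot_longer(x$outputs, -1, names_to = "metric",
                      values_to = "output") |>
    dplyr::rename(value = 1) |>
    dplyr::mutate(parameter = x$parameter, .before = 1)
}

#' Sensitivity factors as a one-row summary
#'
#' @param x A `sensitivity_result`.
#' @param ... Unused.
#' @return A one-row tibble of per-metric sensitivity factors.
#' @method glance sensitivity_result
#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble::as_tibble(as.list(x$factors))
}

#' Tidy a recovery report
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @return The per-replicate tibble.
#' @method tidy recovery_report
#' @export
tidy.recovery_report <- function(x, ...) x$replicates

#' Recovery-report summary
#'
#' @param x A `recovery_report`.
#' @param ... Unused.
#' @return The bias/RMSE summary tibble.
#' @method glance recovery_report
#' @export
glance.recovery_report <- function(x, ...) x$summary

#' Plot a simulated plasma curve
#'
#' @param object A `pbpk_simulation`.
#' @param log_y Use a log concentration axis.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pbpk_simulation
#' @export
autoplot.pbpk_simulation <- function(object, log_y = FALSE, ...) {
  g <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(.data$time_h, .data$conc_ug_L)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ug/L)",
                  title = paste("Simulated", object$route, "arm")) +
    ggplot2::theme_minimal()
  if (log_y) g <- g + ggplot2::scale_y_log10()
  g
}

#' Plot dissolution profiles
#'
#' @param object A [dissolution_profile()] or a list of them.
#' @param ... Unused.
#' @return A ggplot of percent dissolved against time, one line per medium.
#' @method autoplot dissolution_profile
#' @export
autoplot.dissolution_profile <- function(object, ...) {
  plot_dissolution(list(object))
}

#' @rdname autoplot.dissolution_profile
#' @param profiles List of dissolution profiles.
#' @export
plot_dissolution <- function(profiles) {
  df <- dplyr::bind_rows(purrr::map(profiles, function(pr) {
    tibble::tibble(time_min = pr$time_min,
                   pct = 100 * pr$dissolved_fraction,
                   medium = attr(pr, "medium_label"))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$pct,
                                   color = .data$medium)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Time (min)", y = "Dissolved (%)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity scan
#'
#' @param object A `sensitivity_result`.
#' @param ... Unused.
#' @return A faceted ggplot of each metric against the scanned parameter.
#' @method autoplot sensitivity_result
#' @export
autoplot.sensitivity_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$value, .data$output)) +
    ggplot2::geom_line(color = "#2c7fb8") + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = object$parameter, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot regional absorption fractions
#'
#' @param sim A `pbpk_simulation`.
#' @return A ggplot bar chart of per-compartment absorbed fractions.
#' @export
plot_regional_fractions <- function(sim) {
  df <- dplyr::mutate(sim$regional_fractions,
                      compartment = factor(.data$compartment,
                                           levels = .data$compartment))
  ggplot2::ggplot(df, ggplot2::aes(.data$compartment, 100 * .data$fraction,
                                   fill = .data$region)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Fraction of dose absorbed (%)",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
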