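#' Non-compartmental analysis of a plasma curve
#'
#' Standard NCA: Cmax/Tmax from the observed points; AUC0-t by the linear
#' trapezoidal rule (a log-down variant is available); terminal slope
#' (lambda_z) by log-linear regression over the suffix of at least
#' `min_lambda_points` post-Tmax points with the best adjusted R-squared;
#' `AUC0-inf = AUC0-t + C_last/lambda_z`; MRT from AUMC/AUC (0-t and 0-inf
#' variants, with the analytic tail on the first moment); CL = dose/AUC0-inf
#' (systemic clearance for i.v., apparent CL/F otherwise); Vd = CL/lambda_z.
#' Relative bioavailability is dose-normalized AUC against the i.v.
#' reference when one is supplied.
#'
#' @param curve A [plasma_curve()]; censored points may be `NA` and are
#'   dropped.
#' @param iv_reference Optional i.v. [plasma_curve()] for relative
#'   bioavailability.
#' @param method `"linear"` or `"log_down"` trapezoid for AUC.
#' @param min_lambda_points Minimum number of terminal points for lambda_z.
#' @return A one-row tibble of class `nca_result`: `cmax` (ug/L), `tmax`
#'   (h), `auc_0t`, `auc_inf` (ug*h/L), `mrt_0t`, `mrt_inf` (h), `lambda_z`
#'   (1/h), `t_half` (h), `cl` (L/h), `vd` (L), `f_rel` (percent, `NA`
#'   without a reference), `lambda_z_points`, `lambda_z_adj_r2`. When no
#'   positive terminal slope exists the extrapolated quantities are `NA` and
#'   the attribute `lambda_z_failed` is set.
#' @examples
#' cv <- plasma_curve(seq(0.25, 12, by = 0.25),
#'                    100 * exp(-0.5 * seq(0.25, 12, by = 0.25)), dose = 1)
#' run_nca(cv)
#' @export
run_nca <- function(curve, iv_reference = NULL, method = "linear",
                    min_lambda_points = 3) {
  method <- match.arg(method, c("linear", "log_down"))
  obs <- dplyr::filter(tibble::as_tibble(curve), !is.na(.data$conc_ug_L))
  if (sum(obs$conc_ug_L > 0) < 5) {
    stop("NCA needs at least 5 positive concentrations", call. = FALSE)
  }
  t <- obs$time_h; y <- obs$conc_ug_L
  dose_ug <- 1000 * attr(curve, "dose")
  # i.v. bolus: back-extrapolate C0 log-linearly from the first two
  # positive samples and include the 0 -> t1 segment, per NCA convention
  if (identical(attr(curve, "route"), "iv") && t[1] > 0 &&
      y[1] > 0 && y[2] > 0 && y[1] > y[2]) {
    c0 <- y[1] * (y[1] / y[2])^(t[1] / (t[2] - t[1]))
    t <- c(0, t)
    y <- c(c0, y)
  }
  i_max <- which.max(y)
  cmax <- y[i_max]; tmax <- t[i_max]
  auc_seg <- function(t, y) {
    if (method == "linear") {
      diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2
    } else {
      y1 <- utils::head(y, -1); y2 <- utils::tail(y, -1); dt <- diff(t)
      ifelse(y2 < y1 & y2 > 0, dt * (y1 - y2) / log(y1 / y2),
             dt * (y1 + y2) / 2)
    }
  }
  auc_0t <- sum(auc_seg(t, y))
  aumc_0t <- sum(auc_seg(t, t * y))
  # lambda_z: best adjusted-R2 suffix of >= min points, excluding Tmax
  cand <- which(t > tmax & y > 0)
  lz <- NULL
  if (length(cand) >= min_lambda_points) {
    fits <- purrr::map(seq_len(length(cand) - min_lambda_points + 1),
                       function(s) {
      idx <- cand[s:length(cand)]
      fit <- stats::lm(log(y[idx]) ~ t[idx])
      slope <- -unname(stats::coef(fit)[2])
      r2 <- suppressWarnings(summary(fit)$adj.r.squared)
      list(slope = slope, adj_r2 = r2, n = length(idx))
    })
    fits <- purrr::keep(fits, ~ is.finite(.x$slope) && .x$slope > 1e-8)
    if (length(fits) > 0) {
      lz <- fits[[which.max(purrr::map_dbl(fits, "adj_r2"))]]
    }
  }
  if (is.null(lz)) {
    out <- tibble::tibble(
      cmax = cmax, tmax = tmax, auc_0t = auc_0t, auc_inf = NA_real_,
      mrt_0t = aumc_0t / auc_0t, mrt_inf = NA_real_, lambda_z = NA_real_,
      t_half = NA_real_, cl = NA_real_, vd = NA_real_, f_rel = NA_real_,
      lambda_z_points = 0L, lambda_z_adj_r2 = NA_real_)
    attr(out, "lambda_z_failed") <- TRUE
    class(out) <- c("nca_result", class(out))
    return(out)
  }
  c_last <- y[length(y)]; t_last <- t[length(t)]
  auc_inf <- auc_0t + c_last / lz$slope
  aumc_inf <- aumc_0t + c_last * t_last / lz$slope + c_last / lz$slope^2
  cl <- dose_ug / auc_inf
  f_rel <- NA_real_
  if (!is.null(iv_reference)) {
    ref <- run_nca(iv_reference, method = method,
                   min_lambda_points = min_lambda_points)
    f_rel <- 100 * (auc_inf / dose_ug) /
      (ref$auc_inf / (1000 * attr(iv_reference, "dose")))
  }
  out <- tibble::tibble(
    cmax = cmax, tmax = tmax, auc_0t = auc_0t, auc_inf = auc_inf,
    mrt_0t = aumc_0t / auc_0t, mrt_inf = aumc_inf / auc_inf,
    lambda_z = lz$slope, t_half = log(2) / lz$slope,
    cl = cl, vd = cl / lz$slope, f_rel = f_rel,
    lambda_z_points = lz$n, lambda_z_adj_r2 = lz$adj_r2)
  class(out) <- c("nca_result", class(out))
  out
}

#' Fold error between an observed and a simulated value
#'
#' Piecewise maximum-ratio accuracy measure: the larger of the two values
#' divided by the smaller, so the result is always >= 1 and symmetric in its
#' arguments; equal values give exactly 1. A prediction is conventionally
#' deemed accurate when the fold error is within 2.
#'
#' @param observed,simulated Positive values (vectorized).
#' @return Fold error(s), >= 1.
#' @examples
#' fold_error(0.62, 0.53)   # 1.17 after rounding to 2 decimals
#' fold_error(59.38, 38.43) # 1.54
#' @export
fold_error <- function(observed, simulated) {
  if (any(observed <= 0) || any(simulated <= 0)) {
    stop("fold error requires strictly positive values", call. = FALSE)
  }
  pmax(observed / simulated, simulated / observed)
}

#' Fold-error validation table
#'
#' Applies [fold_error()] metric-wise to a table of observed and simulated
#' endpoint values and reports the within-2-fold verdict per metric.
#'
#' @param table Data frame with columns `metric`, `observed`, `simulated`.
#' @param criterion Accuracy bound on the fold error.
#' @return The input with `fold_error` and `within_criterion` columns.
#' @export
validate_predictions <- function(table, criterion = 2) {
  stopifnot(all(c("metric", "observed", "simulated") %in% names(table)))
  dplyr::mutate(tibble::as_tibble(table),
                fold_error = fold_error(.data$observed, .data$simulated),
                within_criterion = .data$fold_error <= criterion)
}

#' Parameter sensitivity scan
#'
#' Evaluates a route-simulation function over a uniform grid of one
#' parameter and computes, per exposure metric, the sensitivity factor
#' `(max - min) / max`. The factor lies in \[0, 1); values near 0 mean the
#' output is insensitive over the scanned range.
#'
#' @param engine A function of one numeric argument (the parameter value)
#'   returning a one-row data frame of metrics, e.g. built around
#'   [simulate_route()] + [summarize_exposure()].
#' @param parameter Name of the scanned parameter (label only).
#' @param low,high Scan range, `low < high`.
#' @param n_points Number of grid points, >= 2.
#' @return A list of class `sensitivity_result`: `parameter`, `grid`,
#'   `outputs` (tibble, one row per grid point) and `factors` (named vector
#'   per metric).
#' @examples
#' s <- sensitivity_scan(function(x) data.frame(m = 1 + x), "x", 0, 1, 3)
#' s$factors  # m: 0.5
#' @export
sensitivity_scan <- function(engine, parameter, low, high, n_points = 11) {
  stopifnot(n_points >= 2, low < high)
  grid <- seq(low, high, length.out = n_points)
  outputs <- purrr::map(grid, function(v) {
    out <- tryCatch(engine(v), error = function(e) {
      stop("engine failed at ", parameter, " = ", format(v), ": ",
           conditionMessage(e), call. = FALSE)
    })
    tibble::as_tibble(out)
  })
  outputs <- dplyr::bind_rows(outputs)
  metrics <- names(outputs)[vapply(outputs, is.numeric, logical(1))]
  factors <- vapply(metrics, function(m) {
    v <- outputs[[m]]
    (max(v) - min(v)) / max(v)
  }, numeric(1))
  structure(list(parameter = parameter, grid = grid,
                 outputs = tibble::tibble(!!parameter := grid, outputs),
                 factors = factors),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result>", x$parameter, "over [",
      min(x$grid), ",", max(x$grid), "],", length(x$grid), "points\n")
  print(round(x$factors, 3))
  invisible(x)
}

#' Residence-time sensitivity scan of the film model
#'
#' Convenience wrapper: scans the oral hold time over `[low, high]` minutes
#' with [simulate_route()] on the supralingual arm and reports sensitivity
#' factors for Tmax, Cmax, AUC0-inf and bioavailability.
#'
#' @param p A [parameter_set()].
#' @param scales Calibrated [mucosa_scales()].
#' @param low,high Hold-time range, minutes.
#' @param n_points Grid size.
#' @param ... Passed to [simulate_route()].
#' @return A `sensitivity_result`.
#' @export
residence_time_scan <- function(p, scales, low = 0, high = 10,
                                n_points = 11, ...) {
  engine <- function(hold) {
    sim <- simulate_route(p, route = "supralingual", hold_time = hold,
                          scales = scales, ...)
    s <- summarize_exposure(sim)
    s[, c("tmax", "cmax", "auc_inf", "bioavailability")]
  }
  sensitivity_scan(engine, "hold_time_min", low, high, n_points)
}
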