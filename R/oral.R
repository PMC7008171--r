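#' Mucosal transfer scales
#'
#' Two calibration multipliers standing in for unpublished oral physiology:
#' `uptake_scale` multiplies the saliva-to-epithelium diffusive flux and
#' `transfer_scale` multiplies the epithelium-to-systemic first-order rate.
#' They are calibrated against reported oral-absorption fractions with
#' [calibrate_mucosa_scales()].
#'
#' @param uptake_scale,transfer_scale Nonnegative multipliers.
#' @return An object of class `mucosa_scales`.
#' @export
mucosa_scales <- function(uptake_scale, transfer_scale) {
  stopifnot(uptake_scale >= 0, transfer_scale >= 0)
  structure(list(uptake_scale = uptake_scale,
                 transfer_scale = transfer_scale),
            class = "mucosa_scales")
}

#' Default fasted-beagle oral-cavity physiology
#'
#' Six mucosal compartments sharing one saliva pool. Keratinized sites
#' (gingiva, hard palate, tongue dorsum) carry a thicker epithelium and a
#' 0.25 uptake factor relative to non-keratinized mucosa. As with the gut
#' table, these are literature-plausible values forming the model's
#' calibration surface, overridable via [read_mouth_physiology_csv()].
#'
#' Salivation is stimulated while the film is held: flow starts at
#' `stimulated_ml_min` and decays to `resting_ml_min` with time constant
#' `stimulation_tau_min`, on a `baseline_ml` resting pool.
#'
#' @return A list with `compartments` (tibble: `name`, `area_cm2`,
#'   `thickness_cm`, `keratinized`, `uptake_factor`) and `saliva` (list:
#'   `baseline_ml`, `stimulated_ml_min`, `resting_ml_min`,
#'   `stimulation_tau_min`, `ph`).
#' @export
default_dog_mouth <- function() {
  list(
    compartments = tibble::tibble(
      name = c("buccal", "gingival", "palate", "tongue_top",
               "tongue_bottom", "mouth_floor"),
      area_cm2 = c(30, 16, 16, 16, 11, 11),
      thickness_cm = c(0.007, 0.012, 0.012, 0.012, 0.007, 0.007),
      keratinized = c(FALSE, TRUE, TRUE, TRUE, FALSE, FALSE),
      uptake_factor = c(1, 0.25, 0.25, 0.25, 1, 1)
    ),
    saliva = list(baseline_ml = 1, stimulated_ml_min = 1.2,
                  resting_ml_min = 0.1, stimulation_tau_min = 3, ph = 6.8)
  )
}

validate_mouth_table <- function(mouth) {
  cmp <- mouth$compartments
  req <- c("name", "area_cm2", "thickness_cm", "keratinized", "uptake_factor")
  miss <- setdiff(req, names(cmp))
  if (length(miss) > 0) {
    stop("mouth physiology table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(cmp$area_cm2 > 0), all(cmp$thickness_cm > 0),
            all(cmp$uptake_factor >= 0),
            mouth$saliva$baseline_ml > 0,
            mouth$saliva$stimulated_ml_min >= 0,
            mouth$saliva$resting_ml_min >= 0,
            mouth$saliva$stimulation_tau_min > 0)
  invisible(mouth)
}

#' Read a mouth physiology override table
#'
#' CSV with columns `name, area_cm2, thickness_cm, keratinized,
#' uptake_factor`; saliva parameters are taken from the defaults unless given.
#'
#' @param path CSV file path.
#' @param saliva Optional replacement for the saliva parameter list.
#' @return A mouth physiology list as from [default_dog_mouth()].
#' @export
read_mouth_physiology_csv <- function(path, saliva = NULL) {
  cmp <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  cmp$keratinized <- as.logical(cmp$keratinized)
  mouth <- list(compartments = cmp,
                saliva = saliva %||% default_dog_mouth()$saliva)
  validate_mouth_table(mouth)
  mouth
}

#' Simulate the oral-cavity hold phase
#'
#' Hold-and-swallow kinetics for a film deposited supralingually (tongue
#' dorsum) or sublingually (tongue underside and mouth floor): the film
#' dissolves in the saliva pool by z-factor kinetics; dissolved drug
#' enters each permeable epithelium by a free-concentration-gradient
#' diffusive flux (`area * D/delta * (fu_plasma * C_saliva - fu_tissue *
#' C_surface) * uptake_scale`, with the deposition site facing the film's
#' saturated boundary layer while undissolved film remains); the epithelium
#' is resolved as a free-drug diffusion chain whose sublayers drain into the
#' systemic circulation at first-order rate `D*fu_tissue/h^2 *
#' transfer_scale`, continuing after the hold; saliva volume accrues by
#' (stimulated, decaying) secretion during the hold with swallowing
#' suppressed; at hold end the saliva content is swallowed as a single bolus
#' and thereafter fresh saliva clears shallow tissue drug back to the gut.
#'
#' @param p A [parameter_set()].
#' @param mouth Mouth physiology list, see [default_dog_mouth()].
#' @param scales A [mucosa_scales()] object.
#' @param site `"supralingual"` or `"sublingual"`.
#' @param hold_time Oral residence time, minutes.
#' @param z Dissolution coefficient, ml/(mg*min), or `z_factor`.
#' @param horizon_h Integration horizon, hours.
#' @return A list of class `oral_simulation`: `trajectory` (oral states over
#'   time), `swallow_schedule` (tibble: the terminal bolus, split by state),
#'   `systemic_flux` (function of time, ug/h, mucosa-to-systemic), and the
#'   simulation context.
#' @export
simulate_oral_hold <- function(p, mouth = default_dog_mouth(),
                               scales, site = "supralingual", hold_time = 2,
                               z = default_film_z(), horizon_h = 32) {
  if (!site %in% c("supralingual", "sublingual")) {
    stop("unknown deposition site: ", site, call. = FALSE)
  }
  stopifnot(hold_time >= 0)
  sim <- simulate_coupled(p, route = site, hold_time = hold_time,
                          scales = scales, z = z, mouth = mouth,
                          times = default_output_grid(horizon_h, hold_time))
  traj <- sim$trajectory
  oral_cols <- c("time_h", "saliva_volume_ml", "or_undis", "or_dis",
                 grep("^or_tis_", names(traj), value = TRUE),
                 grep("^or_upt_", names(traj), value = TRUE),
                 "or_uptake_total", "or_sys_cum", "or_fpe_cum",
                 "swallowed_cum")
  sysflux <- c(0, diff(traj$or_sys_cum + traj$or_fpe_cum) /
                 diff(traj$time_h))
  hold_h <- hold_time / 60
  structure(list(
    trajectory = traj[, oral_cols],
    swallow_schedule = tibble::tibble(
      time_h = hold_h,
      compartment = "stomach",
      state = c("undissolved", "dissolved"),
      amount_ug = as.numeric(sim$swallow_bolus)
    ),
    systemic_flux = stats::approxfun(traj$time_h, sysflux, rule = 2),
    context = sim$context
  ), class = "oral_simulation")
}

#' Fraction of the dose absorbed across the oral mucosa
#'
#' Net amount that crossed the saliva-epithelium interface by the end of
#' the trajectory, as a fraction of the dose. Gross uptake stops at the
#' terminal swallow; afterwards shallow tissue drug is cleared back into
#' (swallowed) fresh saliva, so the net fraction declines from its hold-end
#' peak toward the systemically delivered share. Evaluate on a trajectory
#' integrated to the full horizon (32 h default).
#'
#' @param sim An `oral_simulation` or `pbpk_simulation` object, or a raw
#'   trajectory tibble with an `or_uptake_total` column and dose attribute.
#' @return Fraction in \[0, 1\].
#' @export
oral_absorbed_fraction <- function(sim) {
  traj <- if (is.data.frame(sim)) sim else sim$trajectory
  dose_ug <- if (is.data.frame(sim)) attr(sim, "dose_ug") else
    sim$context$dose_ug
  utils::tail(traj$or_uptake_total, 1) / dose_ug
}

oral_fraction_at_hold <- function(p, mouth, scales, site, hold_time, z,
                                  horizon_h = 10, rtol = 1e-6) {
  # calibration path: short grid over the hold, then coarse to the horizon
  # so the post-swallow clearance of shallow mucosal drug is resolved; the
  # looser tolerance is ample for fractions resolved to 1e-4
  hold_h <- hold_time / 60
  times <- sort(unique(c(seq(0, hold_h, length.out = 8),
                         seq(hold_h, horizon_h, length.out = 20))))
  sim <- simulate_coupled(p, route = site, hold_time = hold_time,
                          scales = scales, z = z, mouth = mouth,
                          times = times, rtol = rtol, atol = 1e-8)
  utils::tail(sim$trajectory$or_uptake_total, 1) / sim$context$dose_ug
}

#' Calibrate the mucosal scales to two oral-absorption anchors
#'
#' Two-parameter root find: `uptake_scale` and `transfer_scale` are adjusted
#' so that the oral absorbed fraction equals `target_2min` at a 2-minute hold
#' and `target_10min` at a 10-minute hold, each within `tol` (absolute).
#' Nested bisection is used — for a trial `transfer_scale`, `uptake_scale` is
#' solved against the 2-minute anchor (the fraction is monotone in
#' `uptake_scale`); the outer root runs on the 10-minute residual, which
#' increases with `transfer_scale` because faster tissue clearance relieves
#' the back-pressure that saturates late uptake.
#'
#' @param p A [parameter_set()].
#' @param target_2min,target_10min Target fractions, `0 < target_2min <
#'   target_10min < 1`.
#' @param mouth Mouth physiology list.
#' @param site Deposition site used for calibration.
#' @param z Dissolution coefficient.
#' @param tol Absolute tolerance on both anchors.
#' @return A [mucosa_scales()] object with attribute `residuals` (named
#'   fractions achieved at 2 and 10 minutes).
#' @export
calibrate_mucosa_scales <- function(p, target_2min = 0.070,
                                    target_10min = 0.195,
                                    mouth = default_dog_mouth(),
                                    site = "supralingual",
                                    z = default_film_z(), tol = 1e-4) {
  if (!(target_2min > 0 && target_2min < target_10min && target_10min < 1)) {
    stop("calibration targets must satisfy 0 < target_2min < target_10min < 1",
         call. = FALSE)
  }
  frac_at <- function(us, ts, hold) {
    oral_fraction_at_hold(p, mouth, mucosa_scales(us, ts), site, hold, z)
  }
  # fast path: damped Broyden iteration on (log uptake, log transfer);
  # the slower nested-bisection path below is the fallback
  broyden <- tryCatch({
    x <- c(0, log(4))
    Fx <- function(x) {
      c(frac_at(exp(x[1]), exp(x[2]), 2) - target_2min,
        frac_at(exp(x[1]), exp(x[2]), 10) - target_10min)
    }
    fx <- Fx(x)
    h <- 0.2
    J <- cbind((Fx(x + c(h, 0)) - fx) / h, (Fx(x + c(0, h)) - fx) / h)
    ok <- FALSE
    for (i in 1:30) {
      if (max(abs(fx)) < tol / 2) { ok <- TRUE; break }
      step <- tryCatch(-solve(J, fx), error = function(e) NULL)
      if (is.null(step)) break
      step <- pmin(1.5, pmax(-1.5, step))
      xn <- x + step
      fn <- Fx(xn)
      if (any(!is.finite(fn))) break
      J <- J + ((fn - fx - J %*% step) %*% t(step)) / sum(step^2)
      x <- xn
      fx <- fn
    }
    if (ok) exp(x) else NULL
  }, error = function(e) NULL)
  if (!is.null(broyden)) {
    out <- mucosa_scales(broyden[1], broyden[2])
    attr(out, "residuals") <- c(
      `2min` = frac_at(broyden[1], broyden[2], 2),
      `10min` = frac_at(broyden[1], broyden[2], 10))
    return(out)
  }
  solve_uptake <- function(ts) {
    f <- function(lus) frac_at(exp(lus), ts, 2) - target_2min
    lo <- log(1e-3); hi <- log(300)
    if (f(lo) > 0 || f(hi) < 0) {
      stop("calibration failure: 2-min anchor not bracketed at ",
           "transfer_scale = ", format(ts), call. = FALSE)
    }
    exp(stats::uniroot(f, c(lo, hi), tol = 1e-3)$root)
  }
  g <- function(lts) {
    ts <- exp(lts)
    us <- solve_uptake(ts)
    frac_at(us, ts, 10) - target_10min
  }
  # the 2-min anchor is unreachable below some transfer_scale; walk the
  # lower bracket end up until the inner solve becomes feasible
  hi <- log(100)
  lo <- NULL
  glo <- NA_real_
  for (cand in log(c(0.25, 0.35, 0.5, 0.7, 1, 1.4, 2, 2.4, 2.8,
                     3.3, 4, 5.7, 8, 16, 32, 64))) {
    val <- tryCatch(g(cand), error = function(e) NULL)
    if (!is.null(val)) {
      lo <- cand
      glo <- val
      break
    }
  }
  if (is.null(lo)) {
    stop("calibration failure: 2-min anchor unreachable for any ",
         "transfer_scale", call. = FALSE)
  }
  ghi <- g(hi)
  if (glo * ghi > 0) {
    stop("calibration failure: 10-min anchor not bracketed; residuals ",
         format(glo, digits = 3), " and ", format(ghi, digits = 3),
         " across the transfer_scale range", call. = FALSE)
  }
  lts <- stats::uniroot(g, c(lo, hi), tol = 1e-3)$root
  ts <- exp(lts)
  us <- solve_uptake(ts)
  achieved <- c(`2min` = frac_at(us, ts, 2), `10min` = frac_at(us, ts, 10))
  if (abs(achieved[1] - target_2min) > tol ||
      abs(achieved[2] - target_10min) > tol) {
    stop("calibration failure: residuals ",
         paste(format(achieved - c(target_2min, target_10min), digits = 3),
               collapse = ", "), call. = FALSE)
  }
  out <- mucosa_scales(us, ts)
  attr(out, "residuals") <- achieved
  out
}
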