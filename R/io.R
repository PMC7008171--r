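#' Read plasma concentration-time curves from CSV
#'
#' Schema: `subject_id, route, time_h, conc_ug_L, dose_mg` (RFC-4180, `\n`
#' or `\r\n` line endings). Rows are grouped by subject and route; times are
#' sorted on read (with a warning if the file was out of order); a duplicate
#' (subject, route, time) triplet is an error naming the offending line.
#'
#' @param path CSV file path.
#' @return A list of [plasma_curve()] objects named `subject_id/route`.
#' @export
read_plasma_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "route", "time_h", "conc_ug_L", "dose_mg")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("plasma CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(df$time_h))) {
    stop("malformed time_h at line(s) ",
         paste(which(!is.finite(df$time_h)) + 1L, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(df$subject_id, df$route, df$time_h)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, route, time) at line ",
         which(duplicated(key))[1] + 1L, call. = FALSE)
  }
  groups <- split(df, paste(df$subject_id, df$route, sep = "/"))
  purrr::imap(groups, function(g, nm) {
    if (is.unsorted(g$time_h)) {
      warning("times for ", nm, " were not sorted; sorting on read",
              call. = FALSE)
      g <- g[order(g$time_h), ]
    }
    plasma_curve(g$time_h, g$conc_ug_L, dose = g$dose_mg[1],
                 route = g$route[1], subject_id = g$subject_id[1])
  })
}

#' Write plasma curves (or a synthetic study) to CSV
#'
#' @param x A `synthetic_study`, a list of [plasma_curve()]s, or a single
#'   curve.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plasma_csv <- function(x, path) {
  df <- if (inherits(x, "synthetic_study")) {
    x$curves
  } else {
    if (inherits(x, "plasma_curve")) x <- list(x)
    dplyr::bind_rows(purrr::map(x, function(cv) {
      tibble::tibble(subject_id = attr(cv, "subject_id"),
                     route = attr(cv, "route"), time_h = cv$time_h,
                     conc_ug_L = cv$conc_ug_L, dose_mg = attr(cv, "dose"))
    }))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read dissolution profiles from CSV
#'
#' Schema: `time_min, pct_dissolved, medium, volume_ml, dose_mg`, one block
#' per medium. `medium_ph` is an optional extra column (NA otherwise).
#'
#' @param path CSV file path.
#' @return A list of [dissolution_profile()] objects, one per medium.
#' @export
read_dissolution_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_min", "pct_dissolved", "medium", "volume_ml", "dose_mg")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("dissolution CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  purrr::map(split(df, df$medium), function(g) {
    g <- g[order(g$time_min), ]
    dissolution_profile(g$time_min, g$pct_dissolved / 100,
                        medium_label = g$medium[1],
                        medium_ph = if ("medium_ph" %in% names(g))
                          g$medium_ph[1] else NA_real_,
                        medium_volume = g$volume_ml[1],
                        initial_dose_mass = g$dose_mg[1])
  })
}

#' Write dissolution profiles to CSV
#'
#' @param profiles A [dissolution_profile()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dissolution_csv <- function(profiles, path) {
  if (inherits(profiles, "dissolution_profile")) profiles <- list(profiles)
  df <- dplyr::bind_rows(purrr::map(profiles, function(pr) {
    tibble::tibble(time_min = pr$time_min,
                   pct_dissolved = 100 * pr$dissolved_fraction,
                   medium = attr(pr, "medium_label"),
                   medium_ph = attr(pr, "medium_ph"),
                   volume_ml = attr(pr, "medium_volume"),
                   dose_mg = attr(pr, "initial_dose_mass"))
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest beside an output file
#'
#' Records the command, the resolved parameter snapshot, package version,
#' seed and timestamp so a run can be reproduced exactly.
#'
#' @param command Command label (e.g. the CLI subcommand and flags).
#' @param p The resolved [parameter_set()].
#' @param out_path The output file the manifest accompanies.
#' @param seed Seed used, or `NULL`.
#' @return Path of the manifest file, invisibly.
#' @export
write_run_manifest <- function(command, p, out_path, seed = NULL) {
  manifest <- list(
    command = command,
    parameters = jsonlite::fromJSON(write_config(p)),
    software_version = as.character(utils::packageVersion("odfpbpk")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  mp <- paste0(out_path, ".manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mp)
}
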