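#' Read a phase response curve from CSV
#'
#' Expects a header with either `phase_rad`/`shift_rad` (radians) or
#' `phase_h`/`shift_h` (circadian hours, period 24); hours are converted to
#' radians and the conversion recorded in the `"unit"` attribute. Phases are
#' canonicalized to `[0, 2*pi)`; shifts must already lie in the wrap range
#' `(-pi, pi]` (+/- 12 h) and out-of-range rows are rejected with their line
#' numbers. Duplicate phases are rejected.
#'
#' @param path CSV path.
#' @return A PRC tibble (`phase_rad`, `shift_rad`) sorted by phase.
#' @export
read_prc_csv <- function(path) {
  # base read.csv: strtod parsing is correctly rounded to the last ulp, which
  # the byte-identical round-trip contract with write_prc_csv relies on
  df <- utils::read.csv(path)
  has_rad <- all(c("phase_rad", "shift_rad") %in% names(df))
  has_h <- all(c("phase_h", "shift_h") %in% names(df))
  if (!has_rad && !has_h) {
    abort("PRC CSV needs columns phase_rad/shift_rad or phase_h/shift_h",
          class = "srclock_unit_missing")
  }
  if (has_rad) {
    phase <- df$phase_rad; shift <- df$shift_rad; unit <- "rad"
  } else {
    phase <- ct_to_rad(df$phase_h); shift <- df$shift_h * 2 * pi / 24; unit <- "hours"
  }
  bad <- which(!is.finite(phase) | !is.finite(shift))
  if (length(bad)) {
    abort(sprintf("non-finite PRC values at data line(s) %s",
                  paste(bad, collapse = ", ")),
          class = "srclock_parse")
  }
  out_of_range <- which(shift > pi + 1e-9 | shift <= -pi - 1e-9)
  if (length(out_of_range)) {
    abort(sprintf("shift outside (-pi, pi] at data line(s) %s",
                  paste(out_of_range, collapse = ", ")),
          class = "srclock_parse")
  }
  phase <- wrap_phase(phase)
  if (anyDuplicated(phase)) {
    abort("duplicate phases in PRC CSV", class = "srclock_parse")
  }
  out <- tibble(phase_rad = phase, shift_rad = shift)
  out <- out[order(out$phase_rad), ]
  attr(out, "unit") <- unit
  out
}

#' Write a phase response curve to CSV
#'
#' Numbers are written with a fixed 17-significant-digit format (the shortest
#' count that round-trips IEEE doubles) so a read/write round trip is
#' byte-identical.
#'
#' @param prc A PRC tibble (`phase_rad`, `shift_rad`).
#' @param path Output path.
#' @param unit `"rad"` (default) or `"hours"`.
#' @return `path`, invisibly.
#' @export
write_prc_csv <- function(prc, path, unit = c("rad", "hours")) {
  unit <- match.arg(unit)
  check_prc(prc)
  if (unit == "rad") {
    df <- data.frame(phase_rad = fmt_num(prc$phase_rad),
                     shift_rad = fmt_num(prc$shift_rad))
  } else {
    df <- data.frame(phase_h = fmt_num(rad_to_ct(prc$phase_rad)),
                     shift_h = fmt_num(prc$shift_rad * 24 / (2 * pi)))
  }
  readr::write_csv(df, path)
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Read a long-format plate CSV with its metadata sidecar
#'
#' The plate CSV has columns `time_h`, `well`, `luminescence` (any row order);
#' the JSON sidecar supplies per-well metadata as a `wells` array of objects
#' with at least `well` and `stim_time_h` (extra fields such as `condition`,
#' `concentration`, `unit` are carried through). Per-well sampling must be
#' uniform within 1% of the sampling interval; a violation is reported naming
#' the well.
#'
#' @param path Plate CSV path.
#' @param sidecar Path of the JSON sidecar (required).
#' @return A list with `plate` (tibble sorted by well and time) and `wells`
#'   (metadata tibble).
#' @export
read_plate_csv <- function(path, sidecar) {
  if (missing(sidecar) || is.null(sidecar) || !file.exists(sidecar)) {
    abort("per-well metadata sidecar (JSON) is required",
          class = "srclock_missing_sidecar")
  }
  plate <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("time_h", "well", "luminescence")
  if (!all(need %in% names(plate))) {
    abort("plate CSV needs columns time_h, well, luminescence",
          class = "srclock_parse")
  }
  plate <- dplyr::arrange(plate, .data$well, .data$time_h)
  meta <- jsonlite::fromJSON(sidecar)
  wells <- as_tibble(if (is.list(meta) && !is.null(meta$wells)) meta$wells else meta)
  if (!all(c("well", "stim_time_h") %in% names(wells))) {
    abort("sidecar must provide `well` and `stim_time_h` per well",
          class = "srclock_missing_sidecar")
  }
  for (w in unique(plate$well)) {
    check_uniform_sampling(plate$time_h[plate$well == w],
                           what = sprintf("well '%s'", w))
  }
  list(plate = as_tibble(plate), wells = wells)
}

#' Write a plate and its sidecar
#'
#' @param plate Long-format plate tibble.
#' @param wells Per-well metadata tibble (must include `well`, `stim_time_h`).
#' @param path Plate CSV path.
#' @param sidecar Sidecar JSON path.
#' @return `path`, invisibly.
#' @export
write_plate_csv <- function(plate, wells, path, sidecar) {
  readr::write_csv(plate, path)
  jsonlite::write_json(list(wells = wells), sidecar, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dose-response table from CSV
#'
#' Columns: `concentration`, `unit`, `R`, optionally `theta_rad`, `replicate`,
#' `condition`, `exclude` (0/1 mask honored by [fit_hill()]). A single
#' concentration unit per table is enforced.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_dose_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("concentration", "R") %in% names(df))) {
    abort("dose CSV needs columns concentration and R", class = "srclock_parse")
  }
  if ("unit" %in% names(df) && length(unique(df$unit)) > 1) {
    abort("dose table mixes concentration units", class = "srclock_parse")
  }
  if (any(df$concentration < 0)) {
    abort("negative concentration in dose table", class = "srclock_parse")
  }
  as_tibble(df)
}

#' Write an SR result as JSON
#'
#' Emits the standard result record:
#' `{R, theta_rad, theta_ct_h, n_support, window, period_h, diagnostics}`.
#'
#' @param sr An [sr_params()] object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sr_json <- function(sr, path) {
  stopifnot(inherits(sr, "sr_params"))
  fit <- sr$diagnostics$fit
  rec <- list(
    R = sr$R,
    theta_rad = if (is.na(sr$theta)) NULL else sr$theta,
    theta_ct_h = if (is.na(sr$theta)) NULL else rad_to_ct(sr$theta),
    n_support = if (is.na(sr$n_support)) NULL else as.integer(sr$n_support),
    window = if (!is.null(fit)) fit$window else NULL,
    period_h = if (!is.null(fit)) fit$period_h else NULL,
    diagnostics = if (!is.null(fit)) list(rss = fit$rss, n = fit$n) else NULL
  )
  jsonlite::write_json(rec[!vapply(rec, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run record for provenance
#'
#' Every CLI invocation writes one of these beside its results: the tool
#' version, timestamp, the parameters used and any warnings captured.
#'
#' @param command Subcommand name.
#' @param params Named list of parameters.
#' @param inputs Character vector of input paths (digested by size).
#' @param warnings Character vector of warnings emitted.
#' @return A named list suitable for [jsonlite::write_json()].
#' @export
run_record <- function(command, params = list(), inputs = character(),
                       warnings = character()) {
  list(
    tool = "srclock",
    version = as.character(utils::packageVersion("srclock")),
    command = command,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = params,
    inputs = lapply(inputs, function(p) {
      list(path = p, bytes = if (file.exists(p)) file.size(p) else NA)
    }),
    warnings = as.list(warnings)
  )
}
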