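#' SR parameters from a phase response curve
#'
#' Evaluates the order-parameter integral
#' `R * exp(1i * Theta) = (1/2pi) * integral of exp(1i * (theta + g(theta)))`
#' by equal-weight quadrature. Given a stimulus, the integrand comes from the
#' circular limit-cycle model on `n_quad` uniform nodes
#' (`theta_j = 2*pi*j/n_quad`); given a sampled PRC, its own (approximately
#' uniform) phases are the nodes.
#'
#' @param x A [stimulus()] or a PRC tibble (`phase_rad`, `shift_rad`).
#' @param n_quad Number of quadrature nodes when `x` is a stimulus.
#' @param theta_floor Passed to [sr_params()].
#' @return An [sr_params()] with `n_support` set to the node count.
#' @examples
#' sr_from_prc(stimulus(0.5, pi / 2), n_quad = 1000)
#' @export
sr_from_prc <- function(x, n_quad = 100, theta_floor = 0.02) {
  if (inherits(x, "stimulus")) {
    if (n_quad < 16) warn("fewer than 16 quadrature nodes: SR estimate is under-sampled",
                          class = "srclock_undersampled")
    prc <- generate_prc(x, n_phases = n_quad)
  } else {
    check_prc(x)
    if (nrow(x) < 16) warn("fewer than 16 PRC samples: SR estimate is under-sampled",
                           class = "srclock_undersampled")
    prc <- x
  }
  z <- mean(exp(1i * (prc$phase_rad + prc$shift_rad)))
  sr_from_complex(z, n_support = nrow(prc), theta_floor = theta_floor)
}

#' SR parameters from single-cell phase-response records
#'
#' The unweighted complex mean of per-cell post-stimulus unit phase vectors,
#' `(1/N) * sum(exp(1i * (theta_j + g(theta_j))))`. Valid as an SR estimate
#' when cell phases at stimulation are approximately uniform.
#'
#' @param records A data frame with one row per cell.
#' @param theta,shift Column names (unquoted) holding the pre-stimulus phase
#'   (radians) and the wrapped phase shift (radians).
#' @inheritParams sr_from_prc
#' @return An [sr_params()] with `n_support = N`.
#' @examples
#' cells <- tibble::tibble(theta_rad = c(0, pi / 2, pi, 3 * pi / 2),
#'                         shift_rad = 0)
#' sr_from_cells(cells)$R  # 0: symmetric cancellation
#' @export
sr_from_cells <- function(records, theta = theta_rad, shift = shift_rad,
                          theta_floor = 0.02) {
  th <- dplyr::pull(records, {{ theta }})
  sh <- dplyr::pull(records, {{ shift }})
  if (length(th) == 0L) abort("no cell records", class = "srclock_empty")
  if (any(!is.finite(th)) || any(!is.finite(sh))) {
    abort("cell records contain non-finite values", class = "srclock_domain")
  }
  z <- mean(exp(1i * (th + sh)))
  sr_from_complex(z, n_support = length(th), theta_floor = theta_floor)
}

#' Half-window sample count for the moving-average detrend
#'
#' Number of sample points within the half-window (default 12 h): at 10-min
#' sampling this is 72, giving a centered 145-point (24-h) window.
#'
#' @param dt_h Sampling interval, hours.
#' @param half_window_h Half of the moving-average window, hours.
#' @return Integer sample count.
#' @export
half_window_n <- function(dt_h, half_window_h = 12) {
  stopifnot(dt_h > 0, half_window_h > 0)
  as.integer(round(half_window_h / dt_h))
}

#' Detrend a bioluminescence series by its 24-h moving average
#'
#' Converts raw luminescence `l_j` to the relative deviation
#' `L_j = (l_j - lbar_j) / lbar_j`, where `lbar_j` is the centered moving
#' average over `2n + 1` points and `n` is the number of points within half
#' the window ([half_window_n()]). The first and last `n` points have no
#' complete window and are dropped. Points where `lbar_j <= 0` are flagged and
#' dropped; the series is rejected if more than 5% of interior points are
#' flagged.
#'
#' @param series A data frame with time and luminescence columns, one well.
#' @param time,value Unquoted column names (defaults `time_h`, `luminescence`).
#' @param window_h Moving-average window, hours (default 24).
#' @param max_flagged Maximum tolerated fraction of nonpositive-average points.
#' @return A tibble with columns `time_h` and `value` (the normalized scale),
#'   attribute `"n_half_window"`.
#' @examples
#' t <- seq(0, 72, by = 1 / 6)
#' raw <- tibble::tibble(time_h = t, luminescence = 100 * (1 + 0.3 * cospi(t / 12)))
#' dt <- detrend(raw)
#' @export
detrend <- function(series, time = time_h, value = luminescence,
                    window_h = 24, max_flagged = 0.05) {
  t <- dplyr::pull(series, {{ time }})
  l <- dplyr::pull(series, {{ value }})
  ord <- order(t)
  t <- t[ord]; l <- l[ord]
  dt <- check_uniform_sampling(t)
  n <- half_window_n(dt, window_h / 2)
  if (length(l) <= 2 * n + 1) {
    abort(sprintf("series too short: need > %d points for a %g-h window",
                  2 * n + 1, window_h),
          class = "srclock_domain")
  }
  lbar <- as.numeric(stats::filter(l, rep(1 / (2 * n + 1), 2 * n + 1), sides = 2))
  keep <- seq.int(n + 1L, length(l) - n)
  t <- t[keep]; l <- l[keep]; lbar <- lbar[keep]
  bad <- lbar <= 0
  if (mean(bad) > max_flagged) {
    abort(sprintf("%.1f%% of points have nonpositive moving average",
                  100 * mean(bad)),
          class = "srclock_divide_by_zero")
  }
  if (any(bad)) warn(sprintf("%d point(s) with nonpositive moving average dropped",
                             sum(bad)))
  out <- tibble(time_h = t[!bad], value = (l[!bad] - lbar[!bad]) / lbar[!bad])
  attr(out, "n_half_window") <- n
  out
}

check_uniform_sampling <- function(t, rel_tol = 0.01, what = "series") {
  d <- diff(t)
  if (length(d) < 1 || any(d <= 0)) {
    abort("time points must be strictly increasing", class = "srclock_domain")
  }
  dt <- median(d)
  if (any(abs(d - dt) > rel_tol * dt)) {
    abort(sprintf("%s is not uniformly sampled (within %g%% of dt = %g h)",
                  what, 100 * rel_tol, dt),
          class = "srclock_nonuniform_sampling")
  }
  dt
}

#' Least-squares cosine fit
#'
#' Fits `value = baseline + amplitude * cos(2*pi*(t - t_ref)/period + acrophase)`
#' on `[t_start, t_end]`. With `period_mode = "fixed24"` the period is held at
#' 24 h and the fit is linear (cosine/sine regression); with `"free"` the
#' period is profiled over `[20, 28]` h by grid search plus golden-section
#' refinement of the residual sum of squares. Negative amplitudes are folded
#' into the acrophase. The acrophase is reported at `t_ref`, so for a
#' post-stimulus rhythm referenced at the stimulus time it is the SR phase.
#'
#' @param series A detrended series ([detrend()] output or any tibble with
#'   `time_h` and a value column).
#' @param t_start,t_end Fit window, hours (defaults: whole series).
#' @param period_mode `"fixed24"` or `"free"`.
#' @param t_ref Reference time for the acrophase (default `t_start`).
#' @param time,value Unquoted column names.
#' @param period_range Search range for the free period, hours.
#' @param noise_floor Window variance below which the fit is refused
#'   (error class `"srclock_degenerate"`).
#' @return An object of class `"cosine_fit"`: amplitude, `acrophase_rad`,
#'   `period_h`, baseline, `rss`, `n`, window.
#' @examples
#' t <- seq(0, 48, by = 1 / 6)
#' d <- tibble::tibble(time_h = t, value = 0.4 * cos(2 * pi * t / 24 + 1))
#' fit_cosine(d)
#' @export
fit_cosine <- function(series, t_start = NULL, t_end = NULL,
                       period_mode = c("fixed24", "free"), t_ref = NULL,
                       time = time_h, value = value,
                       period_range = c(20, 28), noise_floor = 1e-30) {
  period_mode <- match.arg(period_mode)
  t <- dplyr::pull(series, {{ time }})
  y <- dplyr::pull(series, {{ value }})
  t_start <- t_start %||% min(t)
  t_end <- t_end %||% max(t)
  t_ref <- t_ref %||% t_start
  in_win <- t >= t_start - 1e-9 & t <= t_end + 1e-9
  t <- t[in_win]; y <- y[in_win]
  if (length(t) < 8 || diff(range(t)) < 24 - 1e-6) {
    abort("cosine fit needs >= 24 h of data in the window", class = "srclock_domain")
  }
  if (var(y) < noise_floor) {
    abort("window variance below noise floor: no rhythm to fit",
          class = "srclock_degenerate")
  }
  ts <- t - t_ref
  rss_at <- function(period) {
    w <- 2 * pi / period
    X <- cbind(1, cos(w * ts), sin(w * ts))
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }
  if (period_mode == "fixed24") {
    period <- 24
  } else {
    grid <- seq(period_range[1], period_range[2], by = 0.05)
    r <- vapply(grid, rss_at, numeric(1))
    i <- which.min(r)
    lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
    period <- optimize(rss_at, c(lo, hi), tol = 1e-6)$minimum
  }
  w <- 2 * pi / period
  X <- cbind(1, cos(w * ts), sin(w * ts))
  fit <- stats::lm.fit(X, y)
  b <- unname(fit$coefficients)
  amplitude <- sqrt(b[2]^2 + b[3]^2)
  acrophase <- wrap_phase(atan2(-b[3], b[2]))
  structure(
    list(amplitude = amplitude, acrophase_rad = acrophase, period_h = period,
         baseline = b[1], rss = sum(fit$residuals^2), n = length(y),
         window = c(t_start, t_end), t_ref = t_ref,
         period_mode = period_mode),
    class = "cosine_fit"
  )
}

#' @export
print.cosine_fit <- function(x, ...) {
  cat(sprintf(
    "<cosine_fit> amplitude = %.4g, acrophase = %.4f rad, period = %.3f h (%s), n = %d\n",
    x$amplitude, x$acrophase_rad, x$period_h, x$period_mode, x$n))
  invisible(x)
}

#' @rdname fit_cosine
#' @param x A `cosine_fit` object.
#' @param ... Unused.
#' @export
tidy.cosine_fit <- function(x, ...) {
  tibble(
    term = c("amplitude", "acrophase_rad", "period_h", "baseline"),
    estimate = c(x$amplitude, x$acrophase_rad, x$period_h, x$baseline)
  )
}

#' @rdname fit_cosine
#' @export
glance.cosine_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, period_h = x$period_h,
         period_mode = x$period_mode,
         window_start_h = x$window[1], window_end_h = x$window[2])
}

#' Measure the singularity response from a bioluminescence series
#'
#' The direct-measurement pipeline: 24-h moving-average detrend, then a
#' least-squares cosine fit to the post-stimulus rhythm (default window 24-48 h
#' after the stimulus; use `fit_offsets_h = c(24, 96)` for slowly relaxing
#' SCN-style preparations). The SR amplitude is the fitted amplitude on the
#' detrended (relative) scale; the SR phase is the acrophase back-extrapolated
#' to the stimulus time at the fitted period.
#'
#' @param series A data frame with raw `time_h` and `luminescence` for one well.
#' @param stim_time_h Stimulus time, hours from recording start.
#' @param fit_offsets_h Fit window as offsets after the stimulus, hours.
#' @inheritParams fit_cosine
#' @inheritParams detrend
#' @param theta_floor Amplitude below which the SR phase is undefined.
#' @return An [sr_params()] (not restricted to `[0, 1]`: bulk amplitudes live
#'   on the detrended luminescence scale) with the cosine fit attached as
#'   `diagnostics$fit`.
#' @export
measure_sr <- function(series, stim_time_h, fit_offsets_h = c(24, 48),
                       period_mode = c("fixed24", "free"),
                       time = time_h, value = luminescence,
                       window_h = 24, theta_floor = 0.02) {
  period_mode <- match.arg(period_mode)
  det <- detrend(series, time = {{ time }}, value = {{ value }},
                 window_h = window_h)
  fit <- fit_cosine(det,
                    t_start = stim_time_h + fit_offsets_h[1],
                    t_end = stim_time_h + fit_offsets_h[2],
                    period_mode = period_mode, t_ref = stim_time_h)
  sr_params(fit$amplitude, fit$acrophase_rad, n_support = fit$n,
            theta_floor = theta_floor, unit_scale = FALSE,
            diagnostics = list(fit = fit))
}

#' Measure the SR for every well of a plate
#'
#' @param plate Long-format plate data: columns `time_h`, `well`,
#'   `luminescence`.
#' @param wells Per-well metadata with columns `well` and `stim_time_h`
#'   (extra columns are carried through).
#' @param ... Passed to [measure_sr()].
#' @return A tibble with one row per well: metadata plus `R`, `theta_rad`,
#'   `theta_ct_h`, `period_h`.
#' @export
measure_plate_sr <- function(plate, wells, ...) {
  stopifnot(all(c("time_h", "well", "luminescence") %in% names(plate)),
            all(c("well", "stim_time_h") %in% names(wells)))
  res <- purrr::map(seq_len(nrow(wells)), function(i) {
    w <- wells$well[i]
    s <- dplyr::filter(plate, .data$well == w)
    sr <- measure_sr(s, stim_time_h = wells$stim_time_h[i], ...)
    tibble(well = w, R = sr$R, theta_rad = sr$theta,
           theta_ct_h = rad_to_ct(sr$theta),
           period_h = sr$diagnostics$fit$period_h)
  })
  dplyr::left_join(wells, dplyr::bind_rows(res), by = "well")
}
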