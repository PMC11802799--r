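#' Hill dose-response function
#'
#' `H(x) = x^n / (x^n + EC50^n)`: the saturating dose-response curve with
#' half-maximal effective concentration `EC50` and slope (Hill) coefficient
#' `n`. `H(0) = 0`, `H(EC50) = 1/2`, and `H` is strictly increasing and
#' bounded in `[0, 1)`.
#'
#' @param x Concentration(s), >= 0.
#' @param ec50 Half-maximal effective concentration (> 0).
#' @param n Hill slope (> 0).
#' @return Response(s) in `[0, 1)`.
#' @export
hill <- function(x, ec50, n) {
  stopifnot(ec50 > 0, n > 0)
  if (any(x < 0)) abort("concentration must be >= 0", class = "srclock_domain")
  xn <- x^n
  xn / (xn + ec50^n)
}

#' Normalize a dose-response table by its maximal response
#'
#' Divides every response by the largest per-concentration mean response, the
#' convention used when bulk SR amplitudes top out below 1 (single-cell
#' reporter amplitude need not be 1). The maximum is taken over concentration
#' means, not raw replicate points, so a single noisy replicate cannot set the
#' ceiling.
#'
#' @param table A data frame of dose-response rows.
#' @param concentration,response Unquoted column names (defaults
#'   `concentration`, `R`).
#' @return The table with the response column rescaled; the ceiling is attached
#'   as attribute `"r_max"`.
#' @examples
#' tb <- tibble::tibble(concentration = c(1, 10, 100), R = c(0.15, 0.3, 0.6))
#' attr(normalize_by_max(tb), "r_max")  # 0.6
#' @export
normalize_by_max <- function(table, concentration = concentration, response = R) {
  x <- dplyr::pull(table, {{ concentration }})
  y <- dplyr::pull(table, {{ response }})
  if (!any(y > 0)) abort("no positive response in table", class = "srclock_all_zero")
  means <- tapply(y, x, mean)
  r_max <- max(means)
  out <- dplyr::mutate(table, "{{response}}" := {{ response }} / r_max)
  attr(out, "r_max") <- unname(r_max)
  out
}

#' Coefficient of determination
#'
#' `R^2 = 1 - sum((y - f)^2) / sum((y - mean(y))^2)`. Can be negative for fits
#' worse than the constant mean.
#'
#' @param y Observed values.
#' @param f Fitted values (same length).
#' @return A scalar <= 1.
#' @examples
#' r_squared(c(0, 1, 2), c(0, 0, 0))  # -1.5
#' @export
r_squared <- function(y, f) {
  stopifnot(length(y) == length(f), length(y) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) abort("observed values have zero variance",
                         class = "srclock_zero_variance")
  1 - sum((y - f)^2) / ss_tot
}

#' Fit the Hill equation to a dose-response table
#'
#' Least-squares fit of `r_max * H(x; EC50, n)` with `EC50` parameterized in
#' log10 space (bounded to the data range times 1e-2..1e2) and `n` bounded to
#' `(0, 10]`, multi-started from a coarse log-grid so a single bad start cannot
#' trap the fit. Zero-dose rows are excluded (H(0) = 0 exactly; controls serve
#' comparison, not fitting), as are rows with `exclude != 0` when an `exclude`
#' column is present — the explicit per-concentration mask used for
#' non-monotone preparations. A `NON_MONOTONE` warning (class
#' `"srclock_non_monotone"`) is emitted when the mean response at the top dose
#' drops more than 20% below the maximum mean, as with cytotoxic high doses;
#' the fit is still returned.
#'
#' @param table A data frame of dose-response rows.
#' @param concentration,response Unquoted column names (defaults
#'   `concentration`, `R`).
#' @param normalize If `TRUE`, apply [normalize_by_max()] first and record its
#'   ceiling as `r_max`; otherwise responses are taken as already on the
#'   `[0, 1]` scale and `r_max = 1`.
#' @param use_means Fit per-concentration means instead of raw replicates.
#' @return An object of class `"hill_fit"`: `ec50`, `n_hill`, `r_max`, `r2`,
#'   the fitted data, the exclusion mask, and the concentration range.
#' @examples
#' tb <- tibble::tibble(concentration = c(1, 3, 10, 30, 100),
#'                      R = hill(c(1, 3, 10, 30, 100), 10, 1))
#' fit_hill(tb)
#' @export
fit_hill <- function(table, concentration = concentration, response = R,
                     normalize = FALSE, use_means = FALSE) {
  r_max <- 1
  if (normalize) {
    table <- normalize_by_max(table, {{ concentration }}, {{ response }})
    r_max <- attr(table, "r_max")
  }
  x_all <- dplyr::pull(table, {{ concentration }})
  y_all <- dplyr::pull(table, {{ response }})
  excl <- if ("exclude" %in% names(table)) table$exclude != 0 else rep(FALSE, nrow(table))
  keep <- x_all > 0 & !excl
  x <- x_all[keep]; y <- y_all[keep]
  if (length(unique(x)) < 3) {
    abort("need >= 3 distinct nonzero concentrations", class = "srclock_domain")
  }
  if (use_means) {
    m <- tapply(y, x, mean)
    x <- as.numeric(names(m)); y <- as.numeric(m)
  }
  means <- tapply(y, x, mean)
  top <- means[which.max(as.numeric(names(means)))]
  if (top < 0.8 * max(means)) {
    warn("response decreases > 20% at the top dose: non-monotone dose response",
         class = "srclock_non_monotone")
  }
  lb <- c(log10(min(x)) - 2, 1e-3)
  ub <- c(log10(max(x)) + 2, 10)
  sse <- function(p) sum((y - hill(x, 10^p[1], p[2]))^2)
  starts <- expand.grid(
    l = seq(log10(min(x)), log10(max(x)), length.out = 5),
    n = c(0.5, 1, 2, 4)
  )
  fits <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      optim(c(starts$l[i], starts$n[i]), sse, method = "L-BFGS-B",
            lower = lb, upper = ub),
      error = function(e) NULL
    )
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) abort("Hill fit failed to converge from every start",
                               class = "srclock_nonconvergence")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  ec50 <- 10^best$par[1]
  n_hill <- best$par[2]
  fitted <- hill(x, ec50, n_hill)
  extrapolated <- ec50 < min(x) / 100 || ec50 > max(x) * 100
  if (extrapolated) warn("fitted EC50 lies far outside the dosed range",
                         class = "srclock_extrapolated")
  structure(
    list(ec50 = ec50, n_hill = n_hill, r_max = r_max, r2 = r_squared(y, fitted),
         sse = best$value, data = tibble(concentration = x, response = y),
         excluded = x_all[excl], conc_range = range(x),
         normalized = normalize, extrapolated = extrapolated),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf(
    "<hill_fit> EC50 = %.4g, n = %.3f, r_max = %.4g, R^2 = %.4f (n obs = %d)\n",
    x$ec50, x$n_hill, x$r_max, x$r2, nrow(x$data)))
  invisible(x)
}

#' @rdname fit_hill
#' @param x A `hill_fit` object.
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("ec50", "n_hill", "r_max"),
         estimate = c(x$ec50, x$n_hill, x$r_max))
}

#' @rdname fit_hill
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(r2 = x$r2, sse = x$sse, n = nrow(x$data),
         normalized = x$normalized, extrapolated = x$extrapolated)
}

#' Predict the response at given concentrations from a Hill fit
#'
#' @param object A [fit_hill()] object.
#' @param newdata Concentrations to predict at (numeric vector).
#' @param ... Unused.
#' @return Predicted responses on the raw scale (`r_max * H(x)`).
#' @export
predict.hill_fit <- function(object, newdata, ...) {
  object$r_max * hill(newdata, object$ec50, object$n_hill)
}

#' Fit the linear SR-phase vs SR-amplitude relationship
#'
#' The SR phase varies approximately linearly with the SR amplitude for a
#' given stimulus, so a straight line `Theta = a + b * R` fitted on the
#' amplitude range of the data predicts the reset phase at any response level.
#' Phases are unwrapped around their circular mean before ordinary least
#' squares (circular regression is not needed over the modest spans seen in
#' practice); a post-unwrap spread exceeding pi is refused as wrap-ambiguous.
#' Pairs with amplitude below `theta_floor` carry no usable phase and are
#' dropped.
#'
#' @param pairs A data frame of amplitude/phase pairs.
#' @param R,theta Unquoted column names (defaults `R`, `theta_rad`).
#' @param theta_floor Minimum amplitude for a usable phase.
#' @return An object of class `"phase_line"`: intercept `a` (radians), slope
#'   `b` (radians per unit amplitude), amplitude `range`, residuals.
#' @export
fit_phase_line <- function(pairs, R = R, theta = theta_rad, theta_floor = 0.02) {
  r <- dplyr::pull(pairs, {{ R }})
  th <- dplyr::pull(pairs, {{ theta }})
  keep <- is.finite(r) & is.finite(th) & r >= theta_floor
  r <- r[keep]; th <- th[keep]
  if (length(r) < 3) abort("need >= 3 pairs with amplitude above the phase floor",
                           class = "srclock_domain")
  mu <- Arg(mean(exp(1i * th)))
  th_u <- mu + wrap_shift(th - mu)
  if (diff(range(th_u)) > pi) {
    abort("phase spread exceeds pi after unwrapping: line fit is wrap-ambiguous",
          class = "srclock_wrap_ambiguous")
  }
  fit <- lm(th_u ~ r)
  structure(
    list(a = unname(coef(fit)[1]), b = unname(coef(fit)[2]),
         range = range(r), residuals = unname(stats::residuals(fit)),
         n = length(r)),
    class = "phase_line"
  )
}

#' @export
print.phase_line <- function(x, ...) {
  cat(sprintf("<phase_line> theta = %.4f %+.4f * R  (R in [%.3f, %.3f], n = %d)\n",
              x$a, x$b, x$range[1], x$range[2], x$n))
  invisible(x)
}

#' @rdname fit_phase_line
#' @param x A `phase_line` object.
#' @param ... Unused.
#' @export
tidy.phase_line <- function(x, ...) {
  tibble(term = c("intercept_rad", "slope_rad_per_R"), estimate = c(x$a, x$b))
}

#' Predict the phase on a fitted phase-amplitude line
#'
#' @param line A [fit_phase_line()] object.
#' @param R Amplitude(s) to predict at.
#' @return Phase(s) in `[0, 2*pi)`.
#' @export
predict_phase <- function(line, R) {
  stopifnot(inherits(line, "phase_line"))
  wrap_phase(line$a + line$b * R)
}

#' Predict SR parameters at a concentration
#'
#' Combines a Hill amplitude curve and a phase-amplitude line into the
#' four-parameter description of a stimulus: `R = r_max * H(x)` and
#' `Theta = a + b * R`. Composable with [reconstruct_prc()] to emit a predicted
#' PRC at any dose.
#'
#' @param x Concentration (scalar, >= 0).
#' @param hill_fit A [fit_hill()] object.
#' @param line A [fit_phase_line()] object (optional; without it the phase is
#'   undefined).
#' @return An [sr_params()] object. A warning of class
#'   `"srclock_extrapolation"` flags doses outside the fitted range.
#' @export
predict_sr_at_dose <- function(x, hill_fit, line = NULL) {
  stopifnot(inherits(hill_fit, "hill_fit"), length(x) == 1L, x >= 0)
  if (x > 0 && (x < hill_fit$conc_range[1] || x > hill_fit$conc_range[2])) {
    warn("dose outside the fitted concentration range", class = "srclock_extrapolation")
  }
  R <- predict(hill_fit, x)
  theta <- if (is.null(line)) NA_real_ else predict_phase(line, R)
  sr_params(R, theta, unit_scale = FALSE)
}
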