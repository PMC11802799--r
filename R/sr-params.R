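#' Singularity-response parameters
#'
#' The singularity response (SR) of a desynchronized oscillator population is
#' the complex order parameter of the post-stimulus phase distribution:
#' `R * exp(1i * Theta)` with amplitude `R` (mean resultant length, in
#' `[0, 1]` for phase-vector averages) and phase `Theta` (the phase toward
#' which the stimulus resets the clock). When the resultant is shorter than
#' `theta_floor` its argument is noise and `theta` is reported as `NA`.
#'
#' @param R SR amplitude.
#' @param theta SR phase, radians (wrapped to `[0, 2*pi)`); may be `NA`.
#' @param n_support Number of cells/wells/quadrature nodes behind the estimate.
#' @param theta_floor Amplitude below which `theta` is reported as `NA`.
#' @param unit_scale If `TRUE` (phase-vector averages), `R` must lie in
#'   `[0, 1]`; tiny floating-point excursions above 1 are clamped.
#' @param diagnostics Optional named list of fit diagnostics.
#' @return An object of class `"sr_params"`.
#' @examples
#' sr_params(0.5, pi / 2)
#' @export
sr_params <- function(R, theta = NA_real_, n_support = NA_integer_,
                      theta_floor = 0.02, unit_scale = TRUE,
                      diagnostics = list()) {
  stopifnot(is.numeric(R), length(R) == 1L, is.finite(R))
  if (R < 0) abort("SR amplitude must be >= 0", class = "srclock_domain")
  if (unit_scale) {
    if (R > 1 + 1e-9) {
      abort(sprintf("SR amplitude %.6g exceeds 1: not a mean of unit vectors", R),
            class = "srclock_domain")
    }
    R <- min(R, 1)
  }
  theta <- if (is.na(theta) || R < theta_floor) NA_real_ else wrap_phase(theta)
  structure(
    list(R = R, theta = theta, n_support = n_support,
         theta_floor = theta_floor, diagnostics = diagnostics),
    class = "sr_params"
  )
}

sr_from_complex <- function(z, n_support = NA_integer_, theta_floor = 0.02,
                            unit_scale = TRUE, diagnostics = list()) {
  sr_params(Mod(z), Arg(z), n_support = n_support, theta_floor = theta_floor,
            unit_scale = unit_scale, diagnostics = diagnostics)
}

#' @export
print.sr_params <- function(x, ...) {
  th <- if (is.na(x$theta)) "undefined" else
    sprintf("%.4f rad (CT %.2f h)", x$theta, rad_to_ct(x$theta))
  cat(sprintf("<sr_params> R = %.4f, Theta = %s", x$R, th))
  if (!is.na(x$n_support)) cat(sprintf(", n = %d", as.integer(x$n_support)))
  cat("\n")
  invisible(x)
}

#' Complex order parameter of an `sr_params`
#' @param sr An [sr_params()] object.
#' @return A complex scalar `R * exp(1i * theta)` (phase 0 if undefined).
#' @export
as_complex_sr <- function(sr) {
  stopifnot(inherits(sr, "sr_params"))
  th <- if (is.na(sr$theta)) 0 else sr$theta
  complex(modulus = sr$R, argument = th)
}

#' @rdname sr_params
#' @param x An `sr_params` object.
#' @param ... Unused.
#' @export
tidy.sr_params <- function(x, ...) {
  tibble(
    R = x$R,
    theta_rad = x$theta,
    theta_ct_h = rad_to_ct(x$theta),
    n_support = as.integer(x$n_support)
  )
}
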