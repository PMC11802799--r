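#' Combination-model results
#'
#' Predictions for mixed stimuli, background effects and inhibitors are
#' returned as a `"combination"` object: the predicted amplitude (capped at 1
#' where the rule says so, with the cap flagged), the predicted phase, and the
#' rule used. The uncapped complex resultant is retained internally: the cap
#' applies to the reported amplitude only, while the phase and any subsequent
#' background subtraction use the raw sum.
#'
#' @name combination
NULL

new_combination <- function(R_pred, theta_pred, rule, capped = FALSE,
                            raw = NULL, inputs = list()) {
  structure(
    list(R_pred = R_pred, theta_pred = theta_pred, rule = rule,
         capped = capped, raw = raw, inputs = inputs),
    class = "combination"
  )
}

#' @export
print.combination <- function(x, ...) {
  th <- if (is.na(x$theta_pred)) "undefined" else sprintf("%.4f rad", x$theta_pred)
  cat(sprintf("<combination:%s> R = %.4f%s, Theta = %s\n",
              x$rule, x$R_pred, if (x$capped) " (capped at 1)" else "", th))
  invisible(x)
}

#' @rdname combination
#' @param x A `combination` object.
#' @param ... Unused.
#' @export
tidy.combination <- function(x, ...) {
  tibble(R_pred = x$R_pred, theta_pred_rad = x$theta_pred,
         rule = x$rule, capped = x$capped)
}

#' Vector-sum prediction for different-pathway mixed stimuli
#'
#' Stimuli acting through different signaling pathways add as vectors on the
#' limit cycle: `R_AB * exp(1i*Theta_AB) = R_A * exp(1i*Theta_A) +
#' R_B * exp(1i*Theta_B)`. A resultant amplitude above 1 is reported as 1
#' (flagged); the phase always comes from the uncapped sum.
#'
#' @param sr_a,sr_b [sr_params()] objects.
#' @param theta_floor Resultants shorter than this have undefined phase.
#' @return A [combination] object (rule `"vector_sum"`).
#' @examples
#' combine_vector_sum(sr_params(0.3, 0), sr_params(0.4, 0))$R_pred  # 0.7
#' @export
combine_vector_sum <- function(sr_a, sr_b, theta_floor = 0.02) {
  z <- as_complex_sr(sr_a) + as_complex_sr(sr_b)
  R_raw <- Mod(z)
  theta <- if (R_raw < theta_floor) NA_real_ else wrap_phase(Arg(z))
  new_combination(min(R_raw, 1), theta, "vector_sum",
                  capped = R_raw > 1, raw = z,
                  inputs = list(sr_a = sr_a, sr_b = sr_b))
}

#' Equivalent concentration of an SR amplitude under a Hill curve
#'
#' The closed-form inverse of the Hill equation,
#' `x_eq = H^{-1}(R) = EC50 * (R / (1 - R))^(1/n)`: the dose of the reference
#' stimulus that would produce amplitude `R`. Amplitudes are first rescaled by
#' the fit's `r_max` so raw bulk measurements can be inverted against a
#' normalized fit.
#'
#' @param R SR amplitude (raw scale).
#' @param hill_fit A [fit_hill()] object.
#' @param eps_sat Amplitudes with `R / r_max >= 1 - eps_sat` are saturated:
#'   the equivalent dose diverges (error class `"srclock_saturated"`).
#' @return Equivalent concentration (same unit as the fit).
#' @examples
#' tb <- tibble::tibble(concentration = c(1, 10, 100), R = hill(c(1, 10, 100), 10, 1))
#' fit <- fit_hill(tb)
#' equivalent_concentration(0.5, fit)  # EC50 = 10
#' @export
equivalent_concentration <- function(R, hill_fit, eps_sat = 1e-6) {
  stopifnot(inherits(hill_fit, "hill_fit"))
  r <- R / hill_fit$r_max
  if (r < 0) abort("SR amplitude must be >= 0", class = "srclock_domain")
  if (r >= 1 - eps_sat) {
    abort("amplitude at or above the response ceiling: equivalent dose is infinite",
          class = "srclock_saturated")
  }
  hill_fit$ec50 * (r / (1 - r))^(1 / hill_fit$n_hill)
}

#' Equivalent-concentration prediction for same-pathway mixed stimuli
#'
#' Stimuli sharing a signaling pathway do not add as vectors: their amplitudes
#' saturate along the shared Hill curve. Each amplitude is converted to its
#' equivalent dose under the reference fit and the mixture is predicted as
#' `R = H(x_eq_A + x_eq_B)`. The phase, if a [fit_phase_line()] is supplied,
#' comes from the single-stimulus phase-amplitude relationship at the predicted
#' amplitude.
#'
#' @param R_a,R_b SR amplitudes of the two stimuli (raw scale).
#' @param hill_fit Reference [fit_hill()] for the shared pathway.
#' @param line Optional [fit_phase_line()] for the phase prediction.
#' @inheritParams equivalent_concentration
#' @return A [combination] object (rule `"equivalent_conc"`).
#' @examples
#' tb <- tibble::tibble(concentration = c(1, 10, 100), R = hill(c(1, 10, 100), 10, 1))
#' fit <- fit_hill(tb)
#' combine_same_pathway(0.5, 0.5, fit)$R_pred  # H(20) = 2/3
#' @export
combine_same_pathway <- function(R_a, R_b, hill_fit, line = NULL,
                                 eps_sat = 1e-6) {
  x_a <- if (R_a > 0) equivalent_concentration(R_a, hill_fit, eps_sat) else 0
  x_b <- if (R_b > 0) equivalent_concentration(R_b, hill_fit, eps_sat) else 0
  R_pred <- hill_fit$r_max * hill(x_a + x_b, hill_fit$ec50, hill_fit$n_hill)
  theta <- if (is.null(line)) NA_real_ else predict_phase(line, R_pred)
  new_combination(R_pred, theta, "equivalent_conc",
                  inputs = list(R_a = R_a, R_b = R_b, x_eq = c(x_a, x_b)))
}

#' Background (pre-treatment) attenuation of an additional same-type stimulus
#'
#' Resetting reagent already in the medium at concentration `x_bk` consumes
#' part of the Hill curve, so an added dose `x_add` of the same type produces
#' only the difference `R_add = H(x_bk + x_add) - H(x_bk)`. An optional decay
#' factor models loss of the background compound between the two
#' administrations: the effective background is `decay * x_bk`. Named presets:
#' `"none"` (1), `"half"` (0.5), `"third"` (1/3).
#'
#' @param x_bk,x_add Background and additional concentrations (>= 0).
#' @param hill_fit A [fit_hill()] object for the stimulus type.
#' @param decay Multiplicative background decay in `(0, 1]`, or a preset name.
#' @param line Optional [fit_phase_line()] for the phase.
#' @return A [combination] object (rule `"background"`) with the effective
#'   background recorded in `inputs`.
#' @examples
#' tb <- tibble::tibble(concentration = c(1, 10, 100), R = hill(c(1, 10, 100), 10, 1))
#' fit <- fit_hill(tb)
#' background_response(10, 10, fit)$R_pred  # H(20) - H(10) = 1/6
#' @export
background_response <- function(x_bk, x_add, hill_fit, decay = 1, line = NULL) {
  stopifnot(inherits(hill_fit, "hill_fit"), x_bk >= 0, x_add >= 0)
  if (is.character(decay)) {
    decay <- switch(decay,
                    none = 1, half = 0.5, third = 1 / 3,
                    abort(sprintf("unknown decay preset '%s'", decay),
                          class = "srclock_domain"))
  }
  if (decay <= 0 || decay > 1) abort("decay must be in (0, 1]",
                                     class = "srclock_domain")
  eff_bk <- decay * x_bk
  R_pred <- hill_fit$r_max *
    (hill(eff_bk + x_add, hill_fit$ec50, hill_fit$n_hill) -
       hill(eff_bk, hill_fit$ec50, hill_fit$n_hill))
  theta <- if (is.null(line)) NA_real_ else predict_phase(line, R_pred)
  new_combination(R_pred, theta, "background",
                  inputs = list(x_bk = x_bk, x_add = x_add, decay = decay,
                                effective_bk = eff_bk))
}

#' Response to an additional different-type stimulus under a background
#'
#' For different-pathway pairs the final response is the vector sum of the
#' background and the additional stimulus, so the additional stimulus's own SR
#' is the vector difference `sr_final - sr_bk`: a different-type background
#' leaves the added stimulus unchanged. If the final response was capped at 1
#' the difference is biased; a warning of class `"srclock_cap_bias"` is
#' emitted.
#'
#' @param sr_final SR of the combined (background + additional) response: an
#'   [sr_params()] or a capped [combination] result.
#' @param sr_bk SR of the background alone.
#' @param theta_floor Resultants shorter than this have undefined phase.
#' @return A [combination] object (rule `"cross_background"`).
#' @export
cross_background_response <- function(sr_final, sr_bk, theta_floor = 0.02) {
  capped <- inherits(sr_final, "combination") && isTRUE(sr_final$capped)
  z_final <- if (inherits(sr_final, "combination")) {
    complex(modulus = sr_final$R_pred,
            argument = if (is.na(sr_final$theta_pred)) 0 else sr_final$theta_pred)
  } else {
    as_complex_sr(sr_final)
  }
  if (capped) {
    warn("final response was capped at 1: background subtraction is biased low",
         class = "srclock_cap_bias")
  }
  z <- z_final - as_complex_sr(sr_bk)
  R <- Mod(z)
  theta <- if (R < theta_floor) NA_real_ else wrap_phase(Arg(z))
  new_combination(R, theta, "cross_background", capped = FALSE, raw = z,
                  inputs = list(sr_final = sr_final, sr_bk = sr_bk))
}

#' SR parameters of a competitive inhibitor from a background experiment
#'
#' An antagonist added on top of an activating background lowers the final
#' amplitude below the background's own (`R_final < R_bk`), making the nominal
#' additional response negative. The inhibitor's SR amplitude is then the
#' magnitude of that deficit, `R_bk - R_final`, and its SR phase is opposite
#' to the reset phase of the inhibited target (`target_theta + pi`).
#'
#' @param R_final Amplitude of the background + inhibitor response.
#' @param R_bk Amplitude of the background alone.
#' @param target_theta Reset phase of the inhibited target, radians.
#' @return An [sr_params()] for the inhibitor.
#' @examples
#' inhibitor_response(0.2, 0.5, 1.0)  # R = 0.3, Theta = 1 + pi
#' @export
inhibitor_response <- function(R_final, R_bk, target_theta) {
  stopifnot(R_final >= 0, R_bk >= 0)
  if (R_final >= R_bk) {
    abort("final amplitude is not below the background: stimulus is not inhibitory",
          class = "srclock_not_inhibitory")
  }
  sr_params(R_bk - R_final, wrap_phase(target_theta + pi), unit_scale = FALSE)
}
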