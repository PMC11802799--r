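#' Forward amplitude map: stimulus strength to SR amplitude
#'
#' The SR amplitude produced by the circular limit-cycle model at strength `f`,
#' by equal-weight quadrature of `exp(1i * arg(exp(1i*theta) + f*exp(1i*phi)))`
#' over uniform phase nodes. The value does not depend on the stimulus
#' direction, so `phi = 0` is used. `R(0) = 0`, the map is strictly increasing,
#' and it approaches 1 asymptotically without attaining it. The default
#' quadrature (`n_quad = 1e4`) is denser than the 100-node rule sometimes used
#' in spreadsheet solvers (`legacy_quadrature = TRUE` reproduces it), which
#' shows visible bias near the type transition at `f = 1`.
#'
#' @param f Nonnegative stimulus strength(s); vectorized.
#' @param n_quad Number of quadrature nodes.
#' @param legacy_quadrature If `TRUE`, use the historical 100-node spreadsheet rule.
#' @return SR amplitude(s) in `[0, 1)`.
#' @examples
#' forward_amplitude(c(0, 0.5, 2))
#' @export
forward_amplitude <- function(f, n_quad = 1e4, legacy_quadrature = FALSE) {
  if (any(f < 0)) abort("stimulus strength must be >= 0", class = "srclock_domain")
  if (legacy_quadrature) n_quad <- 100
  vapply(f, function(fi) {
    grid <- 2 * pi * seq(0L, n_quad - 1L) / n_quad
    z <- exp(1i * grid) + fi
    if (any(Mod(z) < 1e-9)) {
      # f = 1 puts the node at theta = pi on the singular point; measure-zero
      warn("quadrature node at the singular point; grid shifted by half a step",
           class = "srclock_grid_shift")
      grid <- grid + pi / n_quad
      z <- exp(1i * grid) + fi
    }
    Mod(mean(exp(1i * Arg(z))))
  }, numeric(1))
}

#' Amplitude curve over a strength grid
#'
#' @param f_grid Increasing nonnegative strengths.
#' @inheritParams forward_amplitude
#' @return A tibble with columns `f` and `R`.
#' @export
amplitude_curve <- function(f_grid = seq(0, 3, by = 0.05), n_quad = 1e4) {
  out <- tibble(f = f_grid, R = forward_amplitude(f_grid, n_quad = n_quad))
  attr(out, "n_quad") <- n_quad
  out
}

#' Invert the amplitude map: SR amplitude to stimulus strength
#'
#' Finds the strength `f` with `forward_amplitude(f) = R_target`. The forward
#' map is strictly increasing, so the root is unique; it is bracketed on
#' `[0, f_max]` and found by derivative-free bisection (`uniroot`), which is
#' deterministic where a gradient descent on the squared error needs tuning.
#' The squared error at the solution is attached for reference.
#'
#' @param R_target Target SR amplitude in `[0, 1)`.
#' @param tol Tolerance on the achieved amplitude.
#' @param f_max Upper bound of the search; amplitudes at or above
#'   `forward_amplitude(f_max)` are unattainable (error class
#'   `"srclock_out_of_range"` reporting the achievable ceiling).
#' @inheritParams forward_amplitude
#' @return Strength `f` with attribute `"squared_error"`.
#' @examples
#' invert_amplitude(forward_amplitude(0.7))  # ~0.7
#' @export
invert_amplitude <- function(R_target, tol = 1e-6, f_max = 1e3, n_quad = 1e4) {
  if (R_target < 0) abort("SR amplitude must be >= 0", class = "srclock_domain")
  if (R_target == 0) {
    return(structure(0, squared_error = 0))
  }
  ceiling_R <- forward_amplitude(f_max, n_quad = n_quad)
  if (R_target >= ceiling_R) {
    abort(sprintf(
      "R = %.6g is unattainable: ceiling forward_amplitude(%g) = %.6g (asymptote 1)",
      R_target, f_max, ceiling_R),
      class = "srclock_out_of_range")
  }
  root <- stats::uniroot(
    function(f) forward_amplitude(f, n_quad = n_quad) - R_target,
    interval = c(0, f_max), tol = min(tol, 1e-7) / 10
  )
  f <- root$root
  # refine until the amplitude residual itself is below tol
  lo <- max(0, f - 1e-3); hi <- min(f_max, f + 1e-3)
  while (abs(forward_amplitude(f, n_quad = n_quad) - R_target) >= tol &&
         hi - lo > .Machine$double.eps * max(1, f)) {
    mid <- (lo + hi) / 2
    if (forward_amplitude(mid, n_quad = n_quad) < R_target) lo <- mid else hi <- mid
    f <- (lo + hi) / 2
  }
  structure(f, squared_error = (forward_amplitude(f, n_quad = n_quad) - R_target)^2)
}

#' Reconstruct a phase response curve from SR parameters
#'
#' Inverts the amplitude map to recover the stimulus strength
#' (`f = invert_amplitude(R)`), takes the stimulus direction from the SR phase
#' (`phi = Theta`), and evaluates the circular-model PRC. The round trip
#' `sr_from_prc(reconstruct_prc(sr))` reproduces `sr` to quadrature accuracy.
#' `R = 0` (undefined phase) gives the flat PRC.
#'
#' @param sr An [sr_params()] object, or a list with `R` and `theta`.
#' @param n_phases Number of phases in the reconstructed PRC.
#' @inheritParams invert_amplitude
#' @return A PRC tibble as from [generate_prc()].
#' @export
reconstruct_prc <- function(sr, n_phases = 100, tol = 1e-6, f_max = 1e3,
                            n_quad = 1e4) {
  stopifnot(is.list(sr), !is.null(sr$R))
  if (sr$R == 0) {
    grid <- 2 * pi * seq(0L, n_phases - 1L) / n_phases
    out <- tibble(phase_rad = grid, shift_rad = 0)
    attr(out, "stimulus") <- stimulus(0, 0)
    return(out)
  }
  if (is.na(sr$theta %||% NA_real_)) {
    abort("SR phase is undefined but R > 0: cannot orient the PRC",
          class = "srclock_domain")
  }
  f <- invert_amplitude(sr$R, tol = tol, f_max = f_max, n_quad = n_quad)
  generate_prc(stimulus(as.numeric(f), sr$theta), n_phases = n_phases)
}
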