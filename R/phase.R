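#' Phase and angle utilities
#'
#' Circadian phases are represented internally in radians on the canonical
#' interval `[0, 2*pi)`. Phase *shifts* (differences of phases) are wrapped to
#' `(-pi, pi]`, so the largest representable advance or delay is half a cycle
#' (12 circadian hours). Helpers convert between radians, circadian hours
#' (period 24 h) and cycle fractions.
#'
#' @param theta Numeric vector of angles in radians.
#' @param x Numeric vector of phase differences in radians.
#' @param hours,frac Numeric vectors of phases in circadian hours / cycle
#'   fractions.
#' @param period Circadian period in hours used for the hour conversion.
#' @return Numeric vector of the same length as the input.
#' @examples
#' wrap_phase(-pi / 2)            # 3*pi/2
#' wrap_shift(3 * pi)             # pi
#' rad_to_ct(pi)                  # 12
#' @name phase-utils
NULL

#' @rdname phase-utils
#' @export
wrap_phase <- function(theta) theta %% (2 * pi)

#' @rdname phase-utils
#' @export
wrap_shift <- function(x) {
  w <- x %% (2 * pi)
  ifelse(w > pi, w - 2 * pi, w)
}

#' @rdname phase-utils
#' @export
rad_to_ct <- function(theta, period = 24) theta * period / (2 * pi)

#' @rdname phase-utils
#' @export
ct_to_rad <- function(hours, period = 24) wrap_phase(hours * 2 * pi / period)

#' @rdname phase-utils
#' @export
rad_to_frac <- function(theta) theta / (2 * pi)

#' @rdname phase-utils
#' @export
frac_to_rad <- function(frac) wrap_phase(frac * 2 * pi)

#' Stimulus vector on the limit cycle
#'
#' A stimulus is modeled as a parallel displacement of every on-cycle state by
#' the complex vector `f * exp(1i * phi)`: `f` is the stimulus strength in
#' units of limit-cycle radii and `phi` the direction of the displacement.
#'
#' @param f Nonnegative stimulus strength (limit-cycle radii).
#' @param phi Stimulus direction, radians (canonicalized to `[0, 2*pi)`).
#' @return An object of class `"stimulus"`: a list with elements `f` and `phi`.
#' @examples
#' stimulus(0.5, pi / 2)
#' @export
stimulus <- function(f, phi = 0) {
  stopifnot(is.numeric(f), length(f) == 1L, is.finite(f),
            is.numeric(phi), length(phi) == 1L, is.finite(phi))
  if (f < 0) abort("stimulus strength `f` must be >= 0", class = "srclock_domain")
  structure(list(f = f, phi = wrap_phase(phi)), class = "stimulus")
}

#' @export
print.stimulus <- function(x, ...) {
  cat(sprintf("<stimulus> f = %.4g, phi = %.4g rad (%.2f CT h)\n",
              x$f, x$phi, rad_to_ct(x$phi)))
  invisible(x)
}

#' Apply a stimulus to an on-cycle phase
#'
#' The clock state sits on the unit limit cycle at phase `theta1`; a stimulus
#' displaces it by `f * exp(1i * phi)` and the new phase is the argument of the
#' displaced state:
#' `theta2 = arg(exp(1i * theta1) + f * exp(1i * phi))`.
#' When the displaced state lands at the origin (strength exactly 1, direction
#' antiparallel to the state) the phase is undefined: the clock is at the
#' singular point and an error of class `"srclock_singularity"` is signalled.
#'
#' @param theta1 Numeric vector of pre-stimulus phases, radians.
#' @param stim A [stimulus()], or a numeric strength if `phi` is given.
#' @param phi Stimulus direction when `stim` is given as a bare strength.
#' @param tol_singular Post-stimulus states with magnitude below this value
#'   (in limit-cycle radii) are treated as singular.
#' @return Post-stimulus phases in `[0, 2*pi)`, same length as `theta1`.
#' @examples
#' apply_stimulus(0, stimulus(0.5, pi / 2))  # atan(0.5)
#' @export
apply_stimulus <- function(theta1, stim, phi = NULL, tol_singular = 1e-9) {
  stim <- as_stimulus(stim, phi)
  z <- exp(1i * theta1) + stim$f * exp(1i * stim$phi)
  if (any(Mod(z) < tol_singular)) {
    abort(
      sprintf(
        "singular point reached: post-stimulus magnitude < %g at phase(s) %s",
        tol_singular,
        paste(signif(theta1[Mod(z) < tol_singular], 6), collapse = ", ")
      ),
      class = "srclock_singularity"
    )
  }
  wrap_phase(Arg(z))
}

as_stimulus <- function(stim, phi = NULL) {
  if (inherits(stim, "stimulus")) return(stim)
  stimulus(stim, phi %||% 0)
}

#' Phase shift induced by a stimulus
#'
#' The phase response `g(theta1) = theta2 - theta1`, wrapped to `(-pi, pi]`.
#'
#' @inheritParams apply_stimulus
#' @return Phase shifts in radians, in `(-pi, pi]`.
#' @examples
#' phase_shift(pi, stimulus(2, 0))  # -pi: -1 + 2 lies at angle 0
#' @export
phase_shift <- function(theta1, stim, phi = NULL, tol_singular = 1e-9) {
  stim <- as_stimulus(stim, phi)
  wrap_shift(apply_stimulus(theta1, stim, tol_singular = tol_singular) - theta1)
}

#' Generate a model phase response curve
#'
#' Samples the circular limit-cycle model on a uniform phase grid
#' `theta_j = 2*pi*j/n_phases`, `j = 0, ..., n_phases - 1`. At the type
#' transition (strength exactly 1) a grid node can coincide with the singular
#' pre-phase; the grid is then shifted by half a step with a warning, since the
#' singular input is measure-zero.
#'
#' @inheritParams apply_stimulus
#' @param n_phases Number of uniformly spaced pre-stimulus phases (>= 3).
#' @return A tibble with columns `phase_rad` (pre-stimulus phase) and
#'   `shift_rad` (wrapped phase shift), carrying the generating `f` and `phi`
#'   as attributes `"stimulus"`.
#' @examples
#' prc <- generate_prc(stimulus(0.5, pi / 2), n_phases = 100)
#' max(abs(prc$shift_rad)) < asin(0.5) + 1e-6
#' @export
generate_prc <- function(stim, phi = NULL, n_phases = 100, tol_singular = 1e-9) {
  stim <- as_stimulus(stim, phi)
  stopifnot(n_phases >= 3)
  grid <- 2 * pi * seq(0L, n_phases - 1L) / n_phases
  z <- exp(1i * grid) + stim$f * exp(1i * stim$phi)
  if (any(Mod(z) < tol_singular)) {
    warn("grid node at the singular pre-phase; grid shifted by half a step",
         class = "srclock_grid_shift")
    grid <- grid + pi / n_phases
  }
  shift <- phase_shift(grid, stim, tol_singular = tol_singular)
  out <- tibble(phase_rad = wrap_phase(grid), shift_rad = shift)
  attr(out, "stimulus") <- stim
  out
}

#' Classify a phase response curve as type 1 or type 0
#'
#' Computes the winding number of the post-stimulus phase map
#' `theta2 = theta1 + g(theta1)` around the circle: the sum of wrapped
#' successive differences of `theta2` (including the closing step from the last
#' sample back to the first) divided by `2*pi`, rounded to the nearest integer.
#' Winding 1 is a continuous, type-1 PRC (weak stimulus); winding 0 is a
#' discontinuous, type-0 PRC (strong stimulus). Sampling must resolve the
#' fastest sweep of the map: near the type transition at strength 1 the slope
#' of `theta2` grows like `1/|f - 1|`, so classifying close to the boundary
#' needs correspondingly more phases.
#'
#' @param prc A tibble with columns `phase_rad` and `shift_rad`, sampled on at
#'   least 16 approximately uniform phases, e.g. from [generate_prc()].
#' @param ambiguity_tol The winding sum (in turns) must be within this distance
#'   of an integer; otherwise the PRC is under-sampled and an error of class
#'   `"srclock_ambiguous"` is signalled.
#' @return `"type1"` or `"type0"` (character scalar).
#' @examples
#' classify_prc(generate_prc(stimulus(0.5, 0), n_phases = 128))  # "type1"
#' classify_prc(generate_prc(stimulus(2.0, 0), n_phases = 128))  # "type0"
#' @export
classify_prc <- function(prc, ambiguity_tol = 0.25) {
  check_prc(prc)
  if (nrow(prc) < 16) {
    abort("PRC must be sampled on >= 16 phases for classification",
          class = "srclock_undersampled")
  }
  ord <- order(prc$phase_rad)
  theta2 <- prc$phase_rad[ord] + prc$shift_rad[ord]
  steps <- wrap_shift(diff(theta2))
  closing <- wrap_shift(theta2[1L] - theta2[length(theta2)])
  winding <- (sum(steps) + closing) / (2 * pi)
  k <- round(winding)
  if (abs(winding - k) > ambiguity_tol) {
    abort(sprintf("winding sum %.3f is not close to an integer: under-sampled PRC",
                  winding),
          class = "srclock_ambiguous")
  }
  if (k == 1L) "type1" else if (k == 0L) "type0" else
    abort(sprintf("unexpected winding number %d", k), class = "srclock_ambiguous")
}

check_prc <- function(prc) {
  if (!is.data.frame(prc) || !all(c("phase_rad", "shift_rad") %in% names(prc))) {
    abort("`prc` must be a data frame with columns `phase_rad` and `shift_rad`",
          class = "srclock_domain")
  }
  if (nrow(prc) < 3) abort("PRC needs >= 3 samples", class = "srclock_domain")
  if (any(!is.finite(prc$phase_rad)) || any(!is.finite(prc$shift_rad))) {
    abort("PRC contains non-finite values", class = "srclock_domain")
  }
  if (any(prc$shift_rad > pi + 1e-9) || any(prc$shift_rad <= -pi - 1e-9)) {
    abort("PRC shifts must be wrapped to (-pi, pi]", class = "srclock_domain")
  }
  invisible(prc)
}

#' Locate the type-1 to type-0 transition strength
#'
#' Bisects [classify_prc()] applied to [generate_prc()] between a type-1 and a
#' type-0 bracket. In the circular model the boundary is the singular strength
#' 1. The default grid (`2^15` phases) resolves the winding number down to
#' `|f - 1|` of about `2e-4`, well inside the default bisection tolerance.
#'
#' @param phi Stimulus direction (the boundary does not depend on it).
#' @param f_lo,f_hi Bracketing strengths (must classify type1 / type0).
#' @param tol Absolute tolerance on the returned strength.
#' @param n_phases Phase-grid size used for each classification.
#' @return The transition strength (numeric scalar).
#' @export
find_type_transition <- function(phi = 0, f_lo = 0.5, f_hi = 2,
                                 tol = 1e-3, n_phases = 2^15) {
  cls <- function(f) classify_prc(generate_prc(stimulus(f, phi), n_phases = n_phases))
  if (cls(f_lo) != "type1" || cls(f_hi) != "type0") {
    abort("bracket does not straddle the type transition", class = "srclock_domain")
  }
  while (f_hi - f_lo > tol / 2) {
    mid <- (f_lo + f_hi) / 2
    if (cls(mid) == "type1") f_lo <- mid else f_hi <- mid
  }
  (f_lo + f_hi) / 2
}

#' Stimulus strength that reaches the singular point
#'
#' For a state at phase `theta1` and an antiparallel stimulus direction
#' `phi = theta1 + pi` (for `theta1 = pi/2` this is the direction `-theta1`),
#' minimizes the post-stimulus state magnitude
#' `|exp(1i*theta1) + f*exp(1i*phi)|` over the strength `f` by golden-section
#' search. The minimizer is the strength that cancels the state vector exactly.
#'
#' @param theta1 State phase, radians.
#' @param f_max Upper end of the search interval.
#' @param tol Tolerance on the minimizing strength.
#' @return The minimizing strength (numeric scalar; 1 in the circular model).
#' @export
find_singular_strength <- function(theta1 = 0, f_max = 5, tol = 1e-8) {
  phi <- wrap_phase(theta1 + pi)
  objective <- function(f) Mod(exp(1i * theta1) + f * exp(1i * phi))
  optimize(objective, interval = c(0, f_max), tol = tol)$minimum
}
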