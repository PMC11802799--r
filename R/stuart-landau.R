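#' Stuart-Landau oscillator ensemble
#'
#' The single-cell clock is modeled as a Stuart-Landau oscillator with the
#' imaginary nonlinearity set to zero, so radius and angle decouple:
#' `dR/dt = alpha * (A - R^2) * R` and `dtheta/dt = sigma`. `alpha` is the
#' speed of recovery to the limit cycle (1/h), `sqrt(A)` is the limit-cycle
#' radius (`A = 1` here, so the cycle has radius 1) and `sigma` the angular
#' frequency (`2*pi/24` rad/h for a 24-h clock). Per-oscillator frequencies may
#' differ (period heterogeneity), which makes an initially synchronized
#' population desynchronize spontaneously.
#'
#' @param n Number of oscillators.
#' @param phases Initial angles; default the uniform grid `2*pi*j/n`,
#'   `j = 0, ..., n-1`.
#' @param r Initial radii (default on-cycle, `sqrt(A)`).
#' @param sigma Angular frequency, rad/h; scalar or per-oscillator.
#' @param alpha Radial recovery rate, 1/h.
#' @param A Squared limit-cycle radius.
#' @return An object of class `"sl_ensemble"`.
#' @examples
#' ens <- sl_ensemble(100)
#' collective_output(ens)  # ~0: uniform phases cancel
#' @export
sl_ensemble <- function(n = 100, phases = 2 * pi * seq(0L, n - 1L) / n,
                        r = NULL, sigma = 2 * pi / 24, alpha = 1, A = 1) {
  stopifnot(alpha > 0, A > 0, all(sigma > 0))
  r <- r %||% rep(sqrt(A), length(phases))
  if (length(r) == 1L) r <- rep(r, length(phases))
  if (length(sigma) == 1L) sigma <- rep(sigma, length(phases))
  stopifnot(length(r) == length(phases), length(sigma) == length(phases),
            all(r >= 0))
  structure(
    list(r = r, theta = wrap_phase(phases), sigma = sigma,
         alpha = alpha, A = A),
    class = "sl_ensemble"
  )
}

#' @export
print.sl_ensemble <- function(x, ...) {
  cat(sprintf(
    "<sl_ensemble> %d oscillators, alpha = %g /h, A = %g, mean period = %.2f h\n",
    length(x$r), x$alpha, x$A, mean(2 * pi / x$sigma)))
  invisible(x)
}

#' Evolve an ensemble for a time interval
#'
#' The radial equation is logistic in `u = R^2`, so propagation is closed-form:
#' `u(t) = A * u0 / (u0 + (A - u0) * exp(-2 * alpha * A * t))`; angles advance
#' linearly by `sigma * t`. No integrator error; `R = 0` (the unstable fixed
#' point) propagates exactly.
#'
#' @param ensemble An [sl_ensemble()].
#' @param t Duration, hours (>= 0).
#' @return The evolved ensemble.
#' @export
evolve <- function(ensemble, t) {
  stopifnot(inherits(ensemble, "sl_ensemble"), t >= 0)
  ensemble$r <- sl_radius_at(ensemble$r, t, ensemble$alpha, ensemble$A)
  ensemble$theta <- wrap_phase(ensemble$theta + ensemble$sigma * t)
  ensemble
}

sl_radius_at <- function(r0, t, alpha, A) {
  u0 <- r0^2
  decay <- exp(-2 * alpha * A * t)
  sqrt(A * u0 / (u0 + (A - u0) * decay))
}

#' Displace every oscillator by a stimulus
#'
#' Each state `R_j * exp(1i*theta_j)` moves to `R_j * exp(1i*theta_j) +
#' f * exp(1i*phi)`; radii and angles are read back from the displaced complex
#' states. An oscillator landing exactly at the origin has no defined angle;
#' its angle is re-randomized with a warning (seed the caller for
#' reproducibility).
#'
#' @param ensemble An [sl_ensemble()].
#' @param stim A [stimulus()] (or strength, with `phi`).
#' @param phi Direction when `stim` is a bare strength.
#' @return The displaced ensemble.
#' @export
apply_ensemble_stimulus <- function(ensemble, stim, phi = NULL) {
  stopifnot(inherits(ensemble, "sl_ensemble"))
  stim <- as_stimulus(stim, phi)
  z <- complex(modulus = ensemble$r, argument = ensemble$theta) +
    stim$f * exp(1i * stim$phi)
  at_origin <- Mod(z) < 1e-12
  theta <- wrap_phase(Arg(z))
  if (any(at_origin)) {
    warn(sprintf("%d oscillator(s) displaced to the origin: angle re-randomized",
                 sum(at_origin)),
         class = "srclock_singularity_warning")
    theta[at_origin] <- runif(sum(at_origin), 0, 2 * pi)
  }
  ensemble$r <- Mod(z)
  ensemble$theta <- theta
  ensemble
}

#' Collective output of an ensemble
#'
#' The population analogue of bulk bioluminescence: the average of
#' `R_j * cos(theta_j)` over oscillators.
#'
#' @param ensemble An [sl_ensemble()].
#' @return A numeric scalar.
#' @export
collective_output <- function(ensemble) {
  stopifnot(inherits(ensemble, "sl_ensemble"), length(ensemble$r) >= 1)
  mean(ensemble$r * cos(ensemble$theta))
}

#' Collective output sampled over time
#'
#' Evaluates the closed-form trajectory of every oscillator at each sample time
#' and averages `R_j(t) * cos(theta_j(t))`.
#'
#' @param ensemble An [sl_ensemble()] (state at time 0).
#' @param duration_h Total duration, hours.
#' @param dt_h Sampling interval, hours (default 10 min).
#' @return A tibble with columns `time_h` and `output`.
#' @export
simulate_ensemble_output <- function(ensemble, duration_h, dt_h = 1 / 6) {
  stopifnot(inherits(ensemble, "sl_ensemble"), duration_h > 0, dt_h > 0)
  times <- seq(0, duration_h, by = dt_h)
  # oscillators x times matrices; closed-form radius, linear angle
  u0 <- ensemble$r^2
  decay <- exp(outer(rep(-2 * ensemble$alpha * ensemble$A, length(ensemble$r)),
                     times, `*`))
  r_t <- sqrt(ensemble$A * u0 / (u0 + (ensemble$A - u0) * decay))
  th_t <- outer(ensemble$sigma, times, `*`) + ensemble$theta
  tibble(time_h = times, output = colMeans(r_t * cos(th_t)))
}

#' In-silico SR measurement on a Stuart-Landau ensemble
#'
#' Applies a stimulus at `t = 0` to a uniform-phase on-cycle ensemble, samples
#' the collective output, and cosine-fits the rhythm at `t = 24-48` h after
#' the stimulus (reference time 0, so the acrophase is the SR phase). In the
#' fast-relaxation limit (large `alpha`) the result converges to the circular
#' model's [forward_amplitude()] with `Theta = phi`; slow relaxation biases the
#' measured amplitude, which is the main caveat of the circular approximation.
#'
#' @inheritParams apply_ensemble_stimulus
#' @param alpha,A,n_osc Ensemble parameters (see [sl_ensemble()]).
#' @param dt_h Sampling interval, hours.
#' @param fit_offsets_h Cosine-fit window after the stimulus, hours.
#' @param period_mode Passed to [fit_cosine()].
#' @return An [sr_params()] (amplitude 0 with undefined phase when the output
#'   carries no rhythm, e.g. a zero stimulus).
#' @examples
#' simulate_sr(stimulus(0.5, pi / 2), alpha = 10)
#' @export
simulate_sr <- function(stim, phi = NULL, alpha = 1, A = 1, n_osc = 100,
                        dt_h = 1 / 6, fit_offsets_h = c(24, 48),
                        period_mode = c("fixed24", "free")) {
  period_mode <- match.arg(period_mode)
  stim <- as_stimulus(stim, phi)
  ens <- sl_ensemble(n_osc, alpha = alpha, A = A)
  ens <- apply_ensemble_stimulus(ens, stim)
  traj <- simulate_ensemble_output(ens, duration_h = fit_offsets_h[2], dt_h = dt_h)
  fit <- tryCatch(
    fit_cosine(traj, t_start = fit_offsets_h[1], t_end = fit_offsets_h[2],
               period_mode = period_mode, t_ref = 0,
               time = time_h, value = output),
    srclock_degenerate = function(e) NULL
  )
  if (is.null(fit)) return(sr_params(0, NA_real_, n_support = n_osc))
  sr_params(fit$amplitude, fit$acrophase_rad, n_support = n_osc,
            unit_scale = FALSE, diagnostics = list(fit = fit))
}

#' Synthetic plate protocol
#'
#' Describes a plate of desynchronized wells for the synthetic generator: a
#' stimulus is applied per well (default 96 h after the start of the
#' recording) and the collective rhythm is written as luminescence with a
#' multiplicative exponentially decaying baseline and additive Gaussian
#' measurement noise. All randomness flows from the single `seed`.
#'
#' Two initial conditions are supported. `start = "uniform"` (default) places
#' oscillator phases on the uniform grid `2*pi*j/n_osc`: the state of a
#' culture that has already desynchronized spontaneously by the stimulus time,
#' and the initial condition used for in-silico SR validation. `start =
#' "synchronized"` starts every oscillator at `start_phase_rad`, as after a
#' synchronizing medium change, and exhibits the spontaneous decay of the
#' collective rhythm through period heterogeneity (with a 1-h period SD the
#' dephasing envelope falls to ~58% of initial by 96 h).
#'
#' Defaults emulate a high-throughput luminometer recording: 10-min sampling,
#' 168-h duration, stimulus at 96 h, 200 oscillators per well, 1-h period
#' standard deviation (fibroblast-like), baseline 1000 counts decaying at
#' 1%/h (signal halves in ~3 d as luciferin is consumed), modulation depth 1
#' and noise SD 5 counts.
#'
#' @param stimuli A data frame with one row per well: columns `well`, `f`,
#'   `phi` and optionally `stim_time_h` (default 96).
#' @param n_osc Oscillators per well.
#' @param period_mean_h,period_sd_h Mean and SD of individual periods, hours.
#' @param alpha,A Stuart-Landau parameters.
#' @param start `"uniform"` (desynchronized) or `"synchronized"`.
#' @param start_phase_rad Common initial phase for the synchronized start.
#' @param baseline0 Initial baseline, counts.
#' @param baseline_decay_per_h Exponential baseline decay rate, 1/h.
#' @param mod_depth Multiplicative modulation depth of the collective rhythm.
#' @param noise_sd Additive Gaussian noise SD, counts.
#' @param dt_h Sampling interval, hours.
#' @param duration_h Recording duration, hours (must cover stimulus + 48 h).
#' @param seed Integer seed recorded in the ground truth.
#' @return An object of class `"plate_protocol"`.
#' @export
plate_protocol <- function(stimuli, n_osc = 200, period_mean_h = 24,
                           period_sd_h = 1, alpha = 1, A = 1,
                           start = c("uniform", "synchronized"),
                           start_phase_rad = 0, baseline0 = 1000,
                           baseline_decay_per_h = 0.01, mod_depth = 1,
                           noise_sd = 5, dt_h = 1 / 6, duration_h = 168,
                           seed = 1L) {
  start <- match.arg(start)
  stopifnot(is.data.frame(stimuli), all(c("well", "f", "phi") %in% names(stimuli)))
  if (!"stim_time_h" %in% names(stimuli)) stimuli$stim_time_h <- 96
  if (any(duration_h < stimuli$stim_time_h + 48)) {
    abort("duration must cover every stimulus time + 48 h", class = "srclock_domain")
  }
  stopifnot(n_osc >= 1, period_sd_h >= 0, baseline0 > 0, dt_h > 0)
  structure(
    list(stimuli = as_tibble(stimuli), n_osc = n_osc,
         period_mean_h = period_mean_h, period_sd_h = period_sd_h,
         alpha = alpha, A = A, start = start, start_phase_rad = start_phase_rad,
         baseline0 = baseline0, baseline_decay_per_h = baseline_decay_per_h,
         mod_depth = mod_depth, noise_sd = noise_sd, dt_h = dt_h,
         duration_h = duration_h, seed = as.integer(seed)),
    class = "plate_protocol"
  )
}

#' Generate a synthetic bioluminescence plate
#'
#' Simulates every well of a [plate_protocol()]: per-oscillator periods drawn
#' from a normal law, the configured initial phases (uniform grid by default;
#' optionally synchronized), the stimulus displacement, and luminescence
#' `l(t) = baseline(t) * (1 + mod_depth * mean(R_j * cos(theta_j))) + noise`.
#' Nonpositive luminescence is clipped at 0 with a warning. Output is
#' deterministic given the protocol seed.
#'
#' @param protocol A [plate_protocol()].
#' @return A list with `plate` (tibble `time_h`, `well`, `luminescence`),
#'   `wells` (per-well metadata: `well`, `stim_time_h`, `f`, `phi_rad`,
#'   `predicted_R` from [forward_amplitude()]), and `seed`.
#' @export
generate_plate <- function(protocol) {
  stopifnot(inherits(protocol, "plate_protocol"))
  p <- protocol
  withr::with_seed(p$seed, {
    wells <- purrr::map(seq_len(nrow(p$stimuli)), function(i) {
      row <- p$stimuli[i, ]
      periods <- rnorm(p$n_osc, p$period_mean_h, p$period_sd_h)
      periods <- pmax(periods, 1) # guard absurd draws
      phases0 <- if (p$start == "uniform") {
        2 * pi * seq(0L, p$n_osc - 1L) / p$n_osc
      } else {
        rep(p$start_phase_rad, p$n_osc)
      }
      ens <- sl_ensemble(p$n_osc, phases = phases0,
                         sigma = 2 * pi / periods, alpha = p$alpha, A = p$A)
      pre <- simulate_ensemble_output(ens, duration_h = row$stim_time_h,
                                      dt_h = p$dt_h)
      ens_s <- evolve(ens, row$stim_time_h)
      ens_s <- apply_ensemble_stimulus(ens_s, stimulus(row$f, row$phi))
      post_dur <- p$duration_h - row$stim_time_h
      post <- simulate_ensemble_output(ens_s, duration_h = post_dur, dt_h = p$dt_h)
      x <- c(pre$output, post$output[-1])
      t <- c(pre$time_h, row$stim_time_h + post$time_h[-1])
      baseline <- p$baseline0 * exp(-p$baseline_decay_per_h * t)
      lum <- baseline * (1 + p$mod_depth * x) +
        rnorm(length(t), 0, p$noise_sd)
      if (any(lum < 0)) {
        warn(sprintf("well %s: %d nonpositive luminescence value(s) clipped at 0",
                     row$well, sum(lum < 0)))
        lum <- pmax(lum, 0)
      }
      list(
        series = tibble(time_h = t, well = row$well, luminescence = lum),
        meta = tibble(well = row$well, stim_time_h = row$stim_time_h,
                      f = row$f, phi_rad = wrap_phase(row$phi),
                      predicted_R = forward_amplitude(row$f))
      )
    })
  })
  list(
    plate = dplyr::bind_rows(purrr::map(wells, "series")),
    wells = dplyr::bind_rows(purrr::map(wells, "meta")),
    seed = p$seed
  )
}
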