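# Independent oracles, deliberately written as direct transcriptions of the
# defining formulas rather than through the package's code paths.

# Order-parameter integral of the circular model by dense Riemann sum.
oracle_sr_complex <- function(f, phi, n = 1e6) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  z <- complex(real = cos(theta) + f * cos(phi),
               imaginary = sin(theta) + f * sin(phi))
  mean(exp(1i * atan2(Im(z), Re(z))))
}

oracle_forward_amplitude <- function(f, n = 1e6) Mod(oracle_sr_complex(f, 0, n))

# Fixed-step RK4 integrator for the radial equation dR/dt = alpha*(A - R^2)*R.
oracle_radius_rk4 <- function(r0, t_end, alpha, A, dt = 1e-4) {
  deriv <- function(r) alpha * (A - r^2) * r
  r <- r0
  n <- ceiling(t_end / dt)
  h <- t_end / n
  for (i in seq_len(n)) {
    k1 <- deriv(r)
    k2 <- deriv(r + h / 2 * k1)
    k3 <- deriv(r + h / 2 * k2)
    k4 <- deriv(r + h * k3)
    r <- r + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  r
}

# Hill curve written out directly.
oracle_hill <- function(x, ec50, n) x^n / (x^n + ec50^n)
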