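test_that("sr_from_prc reproduces degenerate and complete resets", {
  # no response: uniform unit vectors cancel
  flat <- tibble::tibble(phase_rad = 2 * pi * (0:99) / 100, shift_rad = 0)
  sr0 <- sr_from_prc(flat)
  expect_lt(sr0$R, 1e-12)
  expect_true(is.na(sr0$theta))

  # complete reset to a target phase: all post-phases identical
  target <- 2.1
  full <- tibble::tibble(
    phase_rad = 2 * pi * (0:99) / 100,
    shift_rad = wrap_shift(target - 2 * pi * (0:99) / 100)
  )
  sr1 <- sr_from_prc(full)
  expect_equal(sr1$R, 1, tolerance = 1e-12)
  expect_equal(sr1$theta, target, tolerance = 1e-12)
})

test_that("sr_from_prc agrees with the dense-quadrature oracle", {
  sr <- sr_from_prc(stimulus(0.5, pi / 2), n_quad = 1e4)
  expect_equal(sr$theta, pi / 2, tolerance = 1e-9) # symmetry: Theta = Phi
  expect_equal(sr$R, 0.2586579, tolerance = 1e-4)  # frozen 1e6-node oracle value
  expect_warning(sr_from_prc(stimulus(0.5, 0), n_quad = 8),
                 class = "srclock_undersampled")
})

test_that("SR phase equals the stimulus direction for every strength", {
  for (f in c(0.1, 0.5, 0.9, 1.5, 4)) {
    sr <- sr_from_prc(stimulus(f, 1.1), n_quad = 1e4)
    expect_equal(sr$theta, 1.1, tolerance = 1e-6)
    expect_lte(sr$R, 1)
  }
})

test_that("sr_from_cells is the complex mean of post-stimulus unit vectors", {
  four <- tibble::tibble(theta_rad = c(0, pi / 2, pi, 3 * pi / 2), shift_rad = 0)
  expect_lt(sr_from_cells(four)$R, 1e-12)

  same <- tibble::tibble(theta_rad = runif(50, 0, 2 * pi))
  same$shift_rad <- wrap_shift(1 - same$theta_rad)
  sr <- sr_from_cells(same)
  expect_equal(sr$R, 1, tolerance = 1e-12)
  expect_equal(sr$theta, 1, tolerance = 1e-10)
  expect_identical(sr$n_support, 50L)

  expect_error(sr_from_cells(same[0, ]), class = "srclock_empty")
})

test_that("cell-record estimate converges to the integral estimate", {
  withr::with_seed(42, {
    n <- 1e5
    theta <- runif(n, 0, 2 * pi)
    cells <- tibble::tibble(theta_rad = theta,
                            shift_rad = phase_shift(theta, stimulus(0.5, pi / 2)))
    sr_n <- sr_from_cells(cells)
    # resultant-length sampling error ~ sqrt((1 - R^2) / (2n)) < 3 SE
    se <- sqrt((1 - 0.2586579^2) / (2 * n))
    expect_lt(abs(sr_n$R - 0.2586579), 3 * se + 1e-3)
    expect_equal(sr_n$theta, pi / 2, tolerance = 0.05)
  })
})

test_that("detrend divides out the moving average and drops edges", {
  t <- seq(0, 72, by = 1 / 6)
  n <- half_window_n(1 / 6)
  expect_identical(n, 72L)

  const <- tibble::tibble(time_h = t, luminescence = 50)
  d0 <- detrend(const)
  expect_equal(d0$value, rep(0, nrow(d0)))
  expect_equal(nrow(d0), length(t) - 2 * n)
  expect_equal(range(d0$time_h), c(12, 60))

  rhythmic <- tibble::tibble(time_h = t,
                             luminescence = 100 * (1 + 0.3 * cos(2 * pi * t / 24)))
  d1 <- detrend(rhythmic)
  expect_lt(max(abs(d1$value - 0.3 * cos(2 * pi * d1$time_h / 24))), 0.02)

  expect_error(detrend(const[1:100, ]), class = "srclock_domain")
  neg <- tibble::tibble(time_h = t, luminescence = -1)
  expect_error(detrend(neg), class = "srclock_divide_by_zero")
})

test_that("fit_cosine recovers amplitude, phase and period", {
  t <- seq(0, 48, by = 1 / 6)
  clean <- tibble::tibble(time_h = t, value = 0.4 * cos(2 * pi * t / 24 + 1))
  fit <- fit_cosine(clean, t_ref = 0)
  expect_equal(fit$amplitude, 0.4, tolerance = 1e-9)
  expect_equal(fit$acrophase_rad, 1, tolerance = 1e-6)

  free <- fit_cosine(clean, period_mode = "free", t_ref = 0)
  expect_equal(free$period_h, 24, tolerance = 1e-3)

  withr::with_seed(7, {
    noisy <- dplyr::mutate(clean, value = value + rnorm(dplyr::n(), 0, 0.05))
    fitn <- fit_cosine(noisy, t_ref = 0)
    expect_lt(abs(fitn$amplitude - 0.4), 0.02)
  })

  zero <- tibble::tibble(time_h = t, value = 0)
  expect_error(fit_cosine(zero), class = "srclock_degenerate")
  expect_error(fit_cosine(clean[t < 20, ]), class = "srclock_domain")
})

test_that("tidiers return one-row/one-term tibbles", {
  t <- seq(0, 48, by = 1 / 6)
  fit <- fit_cosine(tibble::tibble(time_h = t, value = cos(2 * pi * t / 24)))
  expect_named(tidy(fit), c("term", "estimate"))
  expect_equal(nrow(glance(fit)), 1L)
  td <- tidy(sr_params(0.5, 1, n_support = 10L))
  expect_equal(td$theta_ct_h, rad_to_ct(1))
})

test_that("measure_sr recovers stimulus phase and strength from a plate", {
  proto <- plate_protocol(
    stimuli = tibble::tibble(well = c("A1", "A2", "A3"),
                             f = c(0, 5, 5),
                             phi = c(0, 1, 1)),
    seed = 11L
  )
  sim <- generate_plate(proto)
  res <- measure_plate_sr(sim$plate, sim$wells)

  # no stimulus: no resynchronization, amplitude stays near the desync floor
  expect_lt(res$R[res$well == "A1"], 0.1)

  # strong reset: amplitude near the ceiling, phase within 0.5 h of phi
  strong <- res[res$well != "A1", ]
  expect_true(all(abs(strong$R - sim$wells$predicted_R[2]) <
                    0.15 * sim$wells$predicted_R[2]))
  dphi <- abs(wrap_shift(strong$theta_rad - 1))
  expect_true(all(rad_to_ct(dphi) < 0.5))

  # two wells, same stimulus, different realizations: reproducible phase
  expect_lt(rad_to_ct(abs(wrap_shift(diff(strong$theta_rad)))), 1)
})

test_that("noiseless generator output round-trips the collective phase", {
  # no heterogeneity, no noise: detrend + cosine fit must hit the phase exactly
  proto <- plate_protocol(
    stimuli = tibble::tibble(well = "W", f = 3, phi = 2.5),
    period_sd_h = 0, noise_sd = 0, seed = 3L
  )
  # f = 3 drives post-stimulus radii up to 4, so 1 + X dips below 0 briefly
  expect_warning(sim <- generate_plate(proto), "clipped")
  sr <- measure_sr(dplyr::filter(sim$plate, well == "W"), stim_time_h = 96)
  expect_lt(rad_to_ct(abs(wrap_shift(sr$theta - 2.5))), 0.2)
})
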