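hill_fit_exact <- function(ec50 = 10, n = 1, r_max = 1) {
  # exact-parameter fit object for hand-arithmetic checks
  x <- c(1, 3, 10, 30, 100) * ec50 / 10
  fit_hill(tibble::tibble(concentration = x,
                          R = r_max * oracle_hill(x, ec50, n)),
           normalize = r_max != 1)
}

test_that("vector sum adds collinear and cancels antiparallel responses", {
  expect_equal(combine_vector_sum(sr_params(0.3, 0), sr_params(0.4, 0))$R_pred, 0.7)
  anti <- combine_vector_sum(sr_params(0.5, 0), sr_params(0.5, pi))
  expect_lt(anti$R_pred, 1e-12)
  expect_true(is.na(anti$theta_pred))

  big <- combine_vector_sum(sr_params(0.8, 0), sr_params(0.8, 0))
  expect_equal(big$R_pred, 1)        # capped
  expect_true(big$capped)
  expect_equal(Mod(big$raw), 1.6)    # uncapped resultant retained
  expect_equal(big$theta_pred, 0)
})

test_that("vector sum is commutative, associative up to the cap, zero-identity", {
  withr::with_seed(5, {
    for (i in 1:20) {
      a <- sr_params(runif(1, 0.05, 0.45), runif(1, 0, 2 * pi))
      b <- sr_params(runif(1, 0.05, 0.45), runif(1, 0, 2 * pi))
      ab <- combine_vector_sum(a, b)
      ba <- combine_vector_sum(b, a)
      expect_equal(ab$R_pred, ba$R_pred)
      expect_equal(ab$theta_pred, ba$theta_pred)
      z <- combine_vector_sum(a, sr_params(0))
      expect_equal(z$R_pred, a$R)
      if (!is.na(z$theta_pred)) expect_equal(z$theta_pred, a$theta)
    }
  })
})

test_that("equivalent concentration inverts the Hill curve exactly", {
  fit <- hill_fit_exact(10, 1)
  expect_equal(equivalent_concentration(0.5, fit), 10, tolerance = 1e-6)
  expect_equal(equivalent_concentration(0.75, fit), 30, tolerance = 1e-5)
  # inverse identity over (0, 1), relative error < 1e-10 given exact parameters
  fit$ec50 <- 10; fit$n_hill <- 1 # pin to exact values for the identity check
  for (x in 10^seq(-2, 3, length.out = 20)) {
    expect_equal(equivalent_concentration(oracle_hill(x, 10, 1), fit), x,
                 tolerance = 1e-10)
  }
  expect_error(equivalent_concentration(1, fit), class = "srclock_saturated")
})

test_that("same-pathway combination saturates along the shared Hill curve", {
  fit <- hill_fit_exact(10, 1)
  fit$ec50 <- 10; fit$n_hill <- 1
  # two half-maximal stimuli: x_eq = 10 each, R = H(20) = 2/3
  both <- combine_same_pathway(0.5, 0.5, fit)
  expect_equal(both$R_pred, 2 / 3, tolerance = 1e-9)
  # zero second dose is the identity
  expect_equal(combine_same_pathway(0.4, 0, fit)$R_pred, 0.4, tolerance = 1e-9)
  # strict subadditivity for n <= 1
  withr::with_seed(8, {
    for (i in 1:20) {
      n <- runif(1, 0.3, 1)
      f <- hill_fit_exact(10, 1)
      f$ec50 <- 10; f$n_hill <- n
      ra <- runif(1, 0.05, 0.45); rb <- runif(1, 0.05, 0.45)
      expect_lt(combine_same_pathway(ra, rb, f)$R_pred, ra + rb)
    }
  })
})

test_that("background attenuation follows the Hill-difference rule", {
  fit <- hill_fit_exact(10, 1)
  fit$ec50 <- 10; fit$n_hill <- 1
  expect_equal(background_response(10, 0, fit)$R_pred, 0)
  expect_equal(background_response(10, 10, fit)$R_pred, 1 / 6, tolerance = 1e-9)
  half <- background_response(10, 10, fit, decay = 0.5)
  expect_equal(half$R_pred, oracle_hill(15, 10, 1) - oracle_hill(5, 10, 1),
               tolerance = 1e-9)
  expect_equal(half$R_pred, 0.6 - 1 / 3, tolerance = 1e-9)
  expect_equal(background_response(10, 10, fit, decay = "half")$R_pred,
               half$R_pred)
  expect_equal(background_response(9, 10, fit, decay = "third")$inputs$effective_bk,
               3, tolerance = 1e-12)

  # positive for any added dose; monotone decreasing in the background for
  # concave Hill curves (n <= 1, the slope range seen for resetting stimuli --
  # a sigmoidal curve with n > 1 amplifies small additions mid-curve instead)
  for (n in c(0.6, 0.8, 1)) {
    f <- hill_fit_exact(10, 1); f$ec50 <- 10; f$n_hill <- n
    for (x_add in c(1, 10, 100)) {
      r <- vapply(c(0, 3, 10, 30, 100),
                  function(bk) background_response(bk, x_add, f)$R_pred,
                  numeric(1))
      expect_true(all(r > 0))
      expect_true(all(diff(r) < 0))
    }
  }
})

test_that("different-type backgrounds cancel out of the final response", {
  a <- sr_params(0.3, 0.7)
  b <- sr_params(0.4, 2.1)
  final <- combine_vector_sum(a, b)
  back <- cross_background_response(
    sr_params(final$R_pred, final$theta_pred, unit_scale = FALSE), a)
  expect_equal(back$R_pred, b$R, tolerance = 1e-12)
  expect_equal(back$theta_pred, b$theta, tolerance = 1e-12)

  none <- cross_background_response(a, sr_params(0))
  expect_equal(none$R_pred, a$R)

  capped <- combine_vector_sum(sr_params(0.8, 0), sr_params(0.8, 0))
  expect_warning(cross_background_response(capped, sr_params(0.8, 0)),
                 class = "srclock_cap_bias")
})

test_that("inhibitor rule flips the target phase and measures the deficit", {
  inh <- inhibitor_response(0.2, 0.5, target_theta = 1.0)
  expect_equal(inh$R, 0.3)
  expect_equal(inh$theta, wrap_phase(1.0 + pi))
  full <- inhibitor_response(0, 0.5, target_theta = 1.0)
  expect_equal(full$R, 0.5)
  expect_error(inhibitor_response(0.5, 0.5, 1), class = "srclock_not_inhibitory")
})

test_that("equivalent-concentration rule beats the vector sum on shared pathways", {
  # ground truth: two agonists of one receptor; responses sit on one Hill curve
  fit <- hill_fit_exact(10, 1)
  fit$ec50 <- 10; fit$n_hill <- 1
  doses <- expand.grid(xa = c(2, 5, 10, 20), xb = c(2, 5, 10, 20))
  errs <- purrr::pmap_dfr(doses, function(xa, xb) {
    R_true <- oracle_hill(xa + xb, 10, 1)
    ra <- oracle_hill(xa, 10, 1); rb <- oracle_hill(xb, 10, 1)
    tibble::tibble(
      eq = combine_same_pathway(ra, rb, fit)$R_pred - R_true,
      vec = combine_vector_sum(sr_params(ra, 1), sr_params(rb, 1))$R_pred - R_true
    )
  })
  expect_lt(sqrt(mean(errs$eq^2)), sqrt(mean(errs$vec^2)))
  expect_lt(sqrt(mean(errs$eq^2)), 1e-6) # exact on shared-pathway ground truth
})
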