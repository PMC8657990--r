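make_linear_trace <- function(slope, n = 121, dt = 5, intercept = 0) {
  t <- seq(0, by = dt, length.out = n)
  new_kinetic_trace_df <- data.frame(time_s = t,
                                     absorbance_490 = intercept + slope * t)
  structure(new_kinetic_trace_df, class = c("kinetic_trace", "data.frame"),
            metadata = list(nucleophile_conc = 0, is_control = TRUE,
                            replicate = 1L, seed = NULL))
}

test_that("initial_rate inverts the optics transform on exact lines", {
  tr <- make_linear_trace(1.2e-3)
  opt <- noiseless_optics()
  for (m in c("tangent", "linear")) {
    ir <- initial_rate(tr, opt, method = m)
    expect_equal(ir$rate, 1.6e-8, tolerance = 1e-9)
  }

  # flat trace: zero rate, flagged
  ir0 <- initial_rate(make_linear_trace(0), opt)
  expect_equal(ir0$rate, 0)
  expect_true(ir0$nonpositive)

  # residual probe absorptivity raises the effective conversion factor
  opt2 <- noiseless_optics(epsilon_FlBA_490 = 1.5e4)
  ir2 <- initial_rate(tr, opt2)
  expect_equal(ir2$rate, 1.2e-3 / 6e4, tolerance = 1e-9)

  expect_error(initial_rate(make_linear_trace(1e-3, n = 4), opt),
               "fewer than 5")
  # the mixing-lag flag trims the window start
  irl <- initial_rate(tr, opt, mixing_lag = TRUE)
  expect_equal(irl$window[1], 30)
})

test_that("donor constant and HNO flux are recovered from a control trace", {
  opt <- noiseless_optics()
  tr <- simulate_trace(ref_rates(), ref_conditions(), opt)
  ir <- initial_rate(tr, opt)

  # the published reference figures: v0 ~ 0.016 uM/s, k_AS ~ 8.0e-4 1/s
  expect_equal(ir$rate * 1e6, 0.016, tolerance = 0.05)
  kas <- estimate_k_as(ir, 20e-6)
  expect_equal(as.numeric(kas), 8.0e-4, tolerance = 0.05)
  # frozen oracle value for this exact pipeline (tangent fit, 5 s sampling)
  expect_equal(as.numeric(kas), 7.86927e-4, tolerance = 1e-4)

  expect_equal(as.numeric(estimate_k_as(0, 20e-6)), 0)
  expect_error(estimate_k_as(1e-8, 0), "> 0")

  expect_equal(hno_flux(8.0e-4, 20e-6) * 1e6, 0.016)
  expect_equal(hno_flux(0, 20e-6), 0)
  expect_equal(hno_flux(8.0e-4, 40e-6), 2 * hno_flux(8.0e-4, 20e-6))
})

test_that("donor stocks are quantitated by Beer-Lambert at 248 nm", {
  expect_equal(as_concentration_from_absorbance(0.83, 1), 1.0e-4)
  expect_equal(as_concentration_from_absorbance(0), 0)
  expect_equal(as_concentration_from_absorbance(0.83, 2),
               as_concentration_from_absorbance(0.83, 1) / 2)
  expect_error(as_concentration_from_absorbance(-0.1), ">= 0")
})

test_that("inhibition points land on the competition line", {
  opt <- noiseless_optics()

  # matched channels: y = 1 at that concentration
  ser <- generate_series(1.8e4, 225e-6, replicates = 1, seed = 4, optics = opt)
  pts <- inhibition_points(ser)
  expect_equal(pts$y, 1, tolerance = 0.03)
  expect_equal(pts$x, 1)

  # printed-constant case: k = 2.2e3 at 1 mM gives y ~ 0.543
  ser2 <- generate_series(2.2e3, 1e-3, replicates = 1, seed = 4, optics = opt)
  pts2 <- inhibition_points(ser2)
  expect_equal(pts2$y, (2.2e3 / 1.8e4) * (1e-3 / 225e-6), tolerance = 0.05)

  # a decaying trace is excluded with a warning
  ser3 <- generate_series(2.2e3, c(5e-4, 1e-3), replicates = 1, seed = 4,
                          optics = opt)
  ser3$inhibited[[1]]$absorbance_490 <-
    rev(ser3$inhibited[[1]]$absorbance_490)
  expect_warning(pts3 <- inhibition_points(ser3), "excluded")
  expect_equal(nrow(pts3), 1)
})

test_that("competition_fit recovers exact and simulated slopes", {
  # exact points through the origin
  pts <- data.frame(x = c(1, 2, 4), y = c(0.5, 1, 2))
  est <- competition_fit(pts, k_O2 = 1.8e4)
  expect_equal(est$slope, 0.5)
  expect_equal(est$k_nucleophile_hat, 9e3)
  expect_identical(est$k_nucleophile_hat, est$slope * est$k_O2)

  expect_error(competition_fit(data.frame(x = c(2, 2), y = c(1, 1.1))),
               "distinct")

  # a clearly affine point set trips the intercept diagnostic
  expect_warning(
    competition_fit(data.frame(x = c(1, 2, 3, 4), y = c(1.5, 2, 2.5, 3))),
    "intercept")

  # noiseless simulate-then-recover across the published range
  for (k_true in c(2.8e2, 2.2e3, 6.8e3, 2.0e4)) {
    ser <- generate_series(k_true, replicates = 1, seed = 13,
                           optics = noiseless_optics())
    est <- estimate_k_nucleophile(ser)
    expect_equal(est$k_nucleophile_hat, k_true, tolerance = 0.05)
  }

  # noisy recovery at default noise stays within 15%
  ser <- generate_series(6.8e3, replicates = 3, seed = 2024)
  est <- suppressWarnings(estimate_k_nucleophile(ser))
  expect_equal(est$k_nucleophile_hat, 6.8e3, tolerance = 0.15)
  expect_length(est$per_replicate_estimates, 3)
  expect_gt(est$k_se, 0)
})

test_that("recovered constants are invariant to the assumed absorptivity", {
  k_true <- 2.2e3
  est <- lapply(c(1, 3.7), function(f) {
    opt <- noiseless_optics(epsilon_FlOH_490 = 7.5e4 * f)
    ser <- generate_series(k_true, replicates = 1, seed = 6, optics = opt)
    estimate_k_nucleophile(ser, optics = opt)
  })
  expect_equal(est[[1]]$k_nucleophile_hat, est[[2]]$k_nucleophile_hat,
               tolerance = 1e-12)
})
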