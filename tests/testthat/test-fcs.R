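test_that("generated curves evaluate the 2D diffusion model exactly", {
  # half-amplitude point: G(tau_D) = 1/(2N)
  expect_equal(generate_fcs_curve(10, 1e-3, lags = 1e-3)$G, 0.05)
  # G -> 1/N at small lags
  expect_equal(generate_fcs_curve(10, 1e-3, lags = 1e-9)$G, 0.1,
               tolerance = 1e-5)
  # direct evaluation of the model
  expect_equal(generate_fcs_curve(8, 2.59e-5, lags = 1e-4)$G,
               (1 / 8) / (1 + 1e-4 / 2.59e-5), tolerance = 1e-12)
  # noiseless generation reproduces the model at every lag, machine precision
  lags <- 10^seq(-6, 0, length.out = 64)
  cv <- generate_fcs_curve(8, 25.875e-6, lags)
  expect_equal(cv$G, (1 / 8) / (1 + lags / 25.875e-6), tolerance = 1e-15)
  expect_error(generate_fcs_curve(-1, 1e-3), "positive")
  expect_error(generate_fcs_curve(8, 0), "positive")
  a <- generate_fcs_curve(8, 1e-4, noise_sd = 0.01, seed = 5)
  b <- generate_fcs_curve(8, 1e-4, noise_sd = 0.01, seed = 5)
  expect_identical(a$G, b$G)
})

test_that("noiseless fits recover N and tau_D to 1e-6 relative", {
  fit <- fit_fcs_2d(generate_fcs_curve(10, 1e-3))
  expect_equal(fit$N, 10, tolerance = 1e-6)
  expect_equal(fit$tau_D, 1e-3, tolerance = 1e-6)
  # model identities at the fitted parameters
  expect_equal(fit$model(0), 1 / fit$N)
  expect_equal(fit$model(fit$tau_D), 1 / (2 * fit$N))
})

test_that("degenerate and invalid curves are rejected", {
  expect_error(fit_fcs_2d(fcs_curve(10^seq(-6, 0, length.out = 16),
                                    rep(0.1, 16))), "no decay")
  expect_error(fit_fcs_2d(fcs_curve(c(1e-4, 2e-4, 3e-4), c(3, 2, 1) / 30)),
               "8 points")
  expect_error(fit_fcs_2d(fcs_curve(seq(1e-4, 12e-4, length.out = 12),
                                    12:1 / 120)), "decades")
  expect_error(fcs_curve(c(2e-4, 1e-4), c(1, 2)), "increasing")
})

test_that("noisy single-curve recovery stays within 5%", {
  cv <- generate_fcs_curve(8, 25.9e-6, noise_sd = 0.002, seed = 1)
  fit <- fit_fcs_2d(cv)
  expect_lt(abs(fit$N / 8 - 1), 0.05)
  expect_lt(abs(fit$tau_D / 25.9e-6 - 1), 0.05)
})

test_that("scaling all lags scales tau_D and leaves N unchanged", {
  lags <- 10^seq(-6, 0, length.out = 48)
  f1 <- fit_fcs_2d(fcs_curve(lags, (1 / 12) / (1 + lags / 5e-4)))
  f2 <- fit_fcs_2d(fcs_curve(lags * 20, (1 / 12) / (1 + lags / 5e-4)))
  expect_equal(f2$tau_D / f1$tau_D, 20, tolerance = 1e-6)
  expect_equal(f2$N, f1$N, tolerance = 1e-8)
})

test_that("repeated noisy fits have <=5% median error and <=2% bias", {
  errN <- errT <- numeric(100)
  for (i in 1:100) {
    cv <- generate_fcs_curve(8, 25.875e-6, noise_sd = 0.02 / 8, seed = i)
    fit <- fit_fcs_2d(cv)
    errN[i] <- fit$N / 8 - 1
    errT[i] <- fit$tau_D / 25.875e-6 - 1
  }
  expect_lt(median(abs(errN)), 0.05)
  expect_lt(median(abs(errT)), 0.05)
  expect_lt(abs(mean(errN)), 0.02)
  expect_lt(abs(mean(errT)), 0.02)
})

test_that("waist calibration inverts tau_D = r0^2 / (4D)", {
  cal <- calibrate_waist(generate_fcs_curve(8, 25.875e-6), D_known = 414)
  expect_equal(cal$r0_nm, sqrt(4 * 414 * 25.875e-6) * 1000, tolerance = 1e-6)
  # quadrupling D doubles r0 at fixed tau_D
  cal4 <- calibrate_waist(generate_fcs_curve(8, 25.875e-6), D_known = 4 * 414)
  expect_equal(cal4$r0_nm / cal$r0_nm, 2, tolerance = 1e-6)
  expect_error(calibrate_waist(generate_fcs_curve(8, 25.875e-6), D_known = 0),
               "positive")
})

test_that("surface density and coverage follow sigma = N/(pi r0^2), phi = sigma L W", {
  # normalisation: N = pi particles in a 1 um waist -> 1 per um^2
  expect_equal(surface_density(pi, 1000)$sigma_um2, 1, tolerance = 1e-12)
  d <- surface_density(8.07, 207)
  expect_equal(d$sigma_um2, 8.07 / (pi * 0.207^2), tolerance = 1e-12)
  expect_equal(d$sigma_um2, 59.95, tolerance = 1e-3)
  expect_equal(d$phi, d$sigma_um2 * 0.070 * 0.055, tolerance = 1e-12)
  # linearity: sigma in N, phi in sigma
  expect_equal(surface_density(2 * 8.07, 207)$sigma_um2, 2 * d$sigma_um2)
  expect_error(surface_density(-1, 207), "positive")
  expect_warning(surface_density(5000, 207), "phi > 1")
})
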