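test_that("binding series follow I = Imax (1 - exp(-a t))", {
  s <- generate_binding_series(100, 0.05, times = c(0, 10, 20, 60, 1e5))
  expect_equal(s$I[1], 0)
  expect_equal(s$I[3], 100 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(s$I[3], 63.212, tolerance = 1e-4)
  expect_equal(s$I[5], 100, tolerance = 1e-6)  # plateau
  expect_error(generate_binding_series(0, 0.05, 1:10), "positive")
})

test_that("binding fits recover parameters exactly (noiseless) and within 5% (noisy)", {
  fit <- fit_binding(generate_binding_series(100, 0.05, seq(2, 120, by = 4)))
  expect_equal(fit$I_max, 100, tolerance = 1e-6)
  expect_equal(fit$a, 0.05, tolerance = 1e-6)
  noisy <- generate_binding_series(100, 0.05, seq(4, 120, by = 4),
                                   noise_sd = 3, seed = 2)
  fitn <- fit_binding(noisy)
  expect_lt(abs(fitn$I_max / 100 - 1), 0.05)
  expect_lt(abs(fitn$a / 0.05 - 1), 0.05)
  expect_error(fit_binding(binding_series(1:10, rep(5, 10))), "constant")
  expect_error(fit_binding(binding_series(1:4, 1:4)), "5 points")
})

test_that("binding fits at SNR 20 recover both parameters with <=5% median error", {
  errI <- errA <- numeric(100)
  for (i in 1:100) {
    s <- generate_binding_series(100, 0.05, seq(4, 120, by = 4),
                                 noise_sd = 5, seed = i)  # SNR = Imax/sd = 20
    fit <- fit_binding(s)
    errI[i] <- abs(fit$I_max / 100 - 1)
    errA[i] <- abs(fit$a / 0.05 - 1)
  }
  expect_lt(median(errI), 0.05)
  expect_lt(median(errA), 0.05)
})

test_that("membrane intensity integrates above-ROI-average pixels and rises with binding", {
  opt0 <- optics_model(membrane_peak = 20, background = 5)
  opt1 <- optics_model(membrane_peak = 120, background = 5)
  i0 <- membrane_intensity(render_guv_slice(std_shape, opt0, noise = NULL))
  i1 <- membrane_intensity(render_guv_slice(std_shape, opt1, noise = NULL))
  expect_gt(i1, i0)
})

make_flux_frames <- function(int_levels, ext = 100) {
  lapply(seq_along(int_levels), function(i) {
    opt <- optics_model(interior_level = int_levels[i], exterior_level = ext,
                        membrane_peak = 150, background = 0)
    render_guv_slice(std_shape, opt, noise = NULL, time = i - 1)
  })
}

test_that("relative import level hits its exact limits", {
  fr <- make_flux_frames(c(100, 0, 10))
  fs <- flux_statistic(fr, center = std_center_px)
  expect_equal(fs$import[1], 0)                 # equilibrated: exactly 0
  expect_equal(fs$import[2], 1, tolerance = 1e-9)  # fully excluded
  expect_equal(fs$import[3], 0.9, tolerance = 1e-9)
})

test_that("import level is invariant under global intensity rescaling", {
  fr <- make_flux_frames(30)
  fr2 <- list(image_frame(fr[[1]]$pixels * 7.3, fr[[1]]$pixel_size))
  expect_equal(flux_statistic(fr, center = std_center_px)$import,
               flux_statistic(fr2, center = std_center_px)$import,
               tolerance = 1e-12)
})

test_that("exterior ROIs that overlap the vesicle are rejected", {
  fr <- make_flux_frames(10)
  expect_error(
    flux_statistic(fr, center = std_center_px, contour = std_shape,
                   out_positions = list(c(255, 255), c(30, 30))),
    "overlaps the vesicle")
  # far-corner defaults pass the same check
  expect_silent(flux_statistic(fr, center = std_center_px, contour = std_shape))
})

test_that("influx stacks match the closed-form import level and decay monotonically", {
  sc <- permeability_scenario(rate = 0.05, onset = 100)
  # ground-truth import at t = 130 is exp(-1.5)
  lv <- guvrafts:::interior_level_at(sc, 130, 0, 100)
  expect_equal((100 - lv) / 100, exp(-1.5), tolerance = 1e-12)
  st <- simulate_influx_stack(std_shape,
                              optics_model(interior_level = 0,
                                           exterior_level = 100,
                                           membrane_peak = 150, background = 0),
                              sc, times = seq(95, 150, by = 5))
  fs <- flux_statistic(st$frames, center = std_center_px)
  expect_equal(fs$import, st$truth$import, tolerance = 1e-6)
  expect_true(all(diff(fs$import) <= 1e-12))  # monotone decay once permeable
  # crosses 0.5 at onset + ln(2)/rate ~ 113.9 min
  below <- st$truth$time[st$truth$import < 0.5][1]
  expect_gt(below, 110); expect_lte(below, 120)
  # non-permeable limit: import stays 1 with an empty interior
  st0 <- simulate_influx_stack(std_shape,
                               optics_model(interior_level = 0,
                                            exterior_level = 100,
                                            membrane_peak = 150, background = 0),
                               permeability_scenario(rate = 0),
                               times = c(0, 50, 100))
  expect_equal(st0$truth$import, rep(1, 3))
  expect_error(simulate_influx_stack(std_shape, optics_model(exterior_level = 1),
                                     sc, times = c(-1, 2)), "non-negative")
})

test_that("FRAP analysis separates sealed from open channels", {
  t <- seq(0, 60, by = 2)
  # sealed: interior drops at bleach (t = 20) and stays down
  sealed <- flux_series(t, I_in = ifelse(t < 20, 80, 8), I_out = rep(100, length(t)))
  fr_s <- frap_analysis(sealed, bleach_time = 20, horizon = 40)
  expect_equal(fr_s$recovery_fraction, 0)
  expect_false(fr_s$recovered)
  # open: first-order refill at rate 0.1/min after the bleach to zero
  refill <- ifelse(t < 20, 80, 80 * (1 - exp(-0.1 * pmax(0, t - 20))))
  open <- flux_series(t, I_in = refill, I_out = rep(100, length(t)))
  fr_o <- frap_analysis(open, bleach_time = 20, horizon = 40)
  expect_equal(fr_o$recovery_fraction, 1 - exp(-4), tolerance = 1e-9)
  expect_true(fr_o$recovered)
  # instant-refill limit: fraction exactly 1
  inst <- flux_series(t, I_in = ifelse(t == 20, 5, 80), I_out = rep(100, length(t)))
  expect_equal(frap_analysis(inst, bleach_time = 20)$recovery_fraction, 1)
  # no bleach event
  flat <- flux_series(t, I_in = rep(80, length(t)), I_out = rep(100, length(t)))
  expect_error(frap_analysis(flat, bleach_time = 20), "no detectable bleach")
})

test_that("cut-off summary brackets the 50% import midpoint", {
  ladder <- list(`0.65` = c(0.01, 0.03), `20` = c(0.04, 0.06),
                 `40` = c(0.25, 0.35), `70` = c(0.45, 0.55),
                 `150` = c(0.88, 0.92), `500` = c(0.9, 0.94),
                 `2000` = c(0.97, 0.99))
  cs <- cutoff_summary(ladder)
  expect_equal(unname(cs$bracket), c(40, 70))
  expect_equal(cs$table$mean[cs$table$mw_kda == 70], 0.5)
  expect_equal(cs$table$sem[cs$table$mw_kda == 40],
               sd(c(0.25, 0.35)) / sqrt(2))
  # all-zero probes: no crossing
  expect_null(cutoff_summary(list(`20` = 0, `70` = 0))$bracket)
  expect_error(cutoff_summary(list(`70` = 0.5)), "2 probes")
})

test_that("FRET proximity ratio orders conformational states by dye distance", {
  sp <- generate_fret_spectra(c("s-DR" = 7.2, "e-DR" = 3.1, "R-s-DR" = 7.2))
  fr <- fret_proximity(sp)
  expect_true(fr$flags[["e_gt_s"]])
  expect_true(fr$flags[["e_gt_Rs"]])
  expect_gt(fr$ratios[["e-DR"]], 0.5)
  expect_lt(fr$ratios[["s-DR"]], 0.5)
  # donor-only spectrum: ratio near 0
  only_d <- generate_fret_spectra(c("s-DR" = 100))   # r >> R0 -> E ~ 0
  expect_lt(fret_proximity(only_d)$ratios[["s-DR"]], 0.01)
  # swapping distances between states inverts the ordering flags
  swapped <- generate_fret_spectra(c("s-DR" = 3.1, "e-DR" = 7.2, "R-s-DR" = 3.1))
  expect_false(fret_proximity(swapped)$flags[["e_gt_s"]])
  # missing band coverage
  narrow <- sp[sp$wavelength < 600, ]
  expect_error(fret_proximity(narrow), "band")
})
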