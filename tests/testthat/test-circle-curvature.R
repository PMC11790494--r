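test_that("Kasa fit recovers exact circles to machine precision", {
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  circ <- fit_reference_circle(cbind(100 * cos(th), 100 * sin(th)))
  expect_equal(circ$center, c(0, 0), tolerance = 1e-9)
  expect_equal(circ$radius, 100, tolerance = 1e-12)
  # three points of an equilateral triangle: circumcircle radius 50
  tri <- cbind(50 * cos(c(0, 2, 4) * pi / 3) + 7, 50 * sin(c(0, 2, 4) * pi / 3) - 3)
  circ3 <- fit_reference_circle(tri)
  expect_equal(circ3$radius, 50, tolerance = 1e-9)
  expect_equal(circ3$center, c(7, -3), tolerance = 1e-9)
})

test_that("Kasa solution minimises the algebraic objective (brute-force check)", {
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  pts <- cbind(110 * cos(th) + 2, 90 * sin(th) - 1)  # ellipse a=110, b=90
  fit <- fit_reference_circle(pts)
  expect_gt(fit$radius, 90)
  expect_lt(fit$radius, 110)
  alg_obj <- function(a, b, cc)
    sum((pts[, 1]^2 + pts[, 2]^2 - 2 * a * pts[, 1] - 2 * b * pts[, 2] - cc)^2)
  cc_fit <- fit$radius^2 - sum(fit$center^2)
  best <- alg_obj(fit$center[1], fit$center[2], cc_fit)
  grid <- expand.grid(a = seq(-3, 5, length.out = 15),
                      b = seq(-5, 3, length.out = 15),
                      cc = cc_fit * seq(0.9, 1.1, length.out = 15))
  brute <- min(mapply(alg_obj, grid$a, grid$b, grid$cc))
  expect_lte(best, brute + 1e-6)
})

test_that("collinear points are rejected", {
  expect_error(fit_reference_circle(cbind(1:10, 2 * (1:10) + 1)), "collinear")
  expect_error(fit_reference_circle(cbind(1, 1)), "3 points")
})

test_that("curvature of a perfect circular trace is exactly 1 and undeformed", {
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  fake <- structure(list(points = cbind(100 * cos(th), 100 * sin(th)),
                         vertices = cbind(100 * cos(th), 100 * sin(th)),
                         origin = c(0, 0), step_deg = 3,
                         settings = trace_settings(), fits = NULL),
                    class = "guv_trace")
  prof <- curvature_profile(fake)
  expect_equal(prof$k, rep(1, 120), tolerance = 1e-10)
  expect_equal(prof$sdk, 0, tolerance = 1e-10)
  expect_false(prof$deformed)
})

test_that("deformed classification flips strictly at the threshold", {
  tr <- trace_of(mode2_shape(0.05))
  prof <- curvature_profile(tr)
  expect_false(curvature_profile(tr, threshold = prof$sdk)$deformed)
  expect_true(curvature_profile(tr, threshold = prof$sdk - 1e-9)$deformed)
  # SD_k above the 0.026 bare-GUV reference => deformed at that threshold
  expect_gt(prof$sdk, 0.026)
  expect_true(curvature_profile(tr, threshold = 0.026)$deformed)
})

test_that("population statistics count deformation efficiency and pool k_i", {
  circ_prof <- curvature_profile(trace_contour(std_image, x_seed = c(355, 255)))
  profs <- c(lapply(c(0.06, 0.08, 0.1, 0.12), function(a)
    curvature_profile(trace_of(mode2_shape(a)))),
    rep(list(circ_prof), 6))
  ps <- population_stats(profs)
  expect_equal(ps$efficiency, 0.4)
  expect_identical(ps$n, 10L)
  expect_equal(sum(ps$hist$counts), 10 * 120)
  # all-undeformed population: efficiency 0, histogram mass at the k = 1 bin
  ps0 <- population_stats(profs[5:10])
  expect_equal(ps0$efficiency, 0)
  mode_bin <- which.max(ps0$hist$counts)
  expect_lt(abs(ps0$hist$mids[mode_bin] - 1), 0.03)
  expect_error(population_stats(list()), "at least one")
})

test_that("deformed populations have broader pooled k_i than undeformed ones", {
  quiet <- rep(list(curvature_profile(trace_contour(std_image,
                                                    x_seed = c(355, 255)))), 4)
  loud <- lapply(seq(0.08, 0.12, length.out = 4), function(a)
    curvature_profile(trace_of(mode2_shape(a))))
  expect_gt(population_stats(loud)$k_pooled_sd,
            population_stats(quiet)$k_pooled_sd)
})

test_that("baseline calibration recovers the mean bare-GUV SD_k", {
  profs <- lapply(c(30, 80, 150) / 10, function(R) {
    shp <- make_contour(R, center = c(25.5, 25.5))
    curvature_profile(trace_of(shp))
  })
  thr <- calibrate_baseline(profs)
  expect_equal(thr, mean(vapply(profs, `[[`, numeric(1), "sdk")))
  expect_lt(thr, 0.005)
})
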