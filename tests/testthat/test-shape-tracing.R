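test_that("adaptive threshold is the regional mean and adapts to the vesicle", {
  flat <- image_frame(matrix(50, 128, 128), 0.1)
  expect_equal(adaptive_threshold(flat, c(64, 64), c(90, 64)), 50)
  # synthetic GUV: background 10, interior 10, ring peak 200; seed on the ring
  opt <- optics_model(interior_level = 0, exterior_level = 0,
                      membrane_peak = 200, background = 10)
  img <- render_guv_slice(std_shape, opt, noise = NULL)
  thr <- adaptive_threshold(img, std_center_px, c(355, 255))
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  # degenerate region
  expect_error(adaptive_threshold(flat, c(64, 64), c(64, 64), extra = 1),
               "degenerate")
  expect_error(adaptive_threshold(flat, c(200, 64), c(64, 64)), "inside")
})

test_that("a noiseless circle is traced with 120 sub-pixel-accurate points", {
  tr <- trace_contour(std_image, x_seed = c(355, 255))
  expect_identical(nrow(tr$points), 120L)
  expect_identical(nrow(tr$vertices), 120L)
  rv <- sqrt((tr$vertices[, 1] - 255)^2 + (tr$vertices[, 2] - 255)^2)
  expect_lt(max(abs(rv - 100)), 0.5)
  # membrane pixels are integer-valued pixel coordinates
  expect_identical(tr$points, round(tr$points))
  # consecutive points subtend ~step_deg at the origin
  ang <- atan2(tr$vertices[, 2] - 255, tr$vertices[, 1] - 255) * 180 / pi
  dd <- diff(ang) %% 360
  expect_true(all(abs(dd - 3) < 1))
})

test_that("point count always equals 360 / step_deg", {
  for (step in c(5, 9, 15)) {
    tr <- trace_contour(std_image, x_seed = c(355, 255),
                        settings = trace_settings(step_deg = step))
    expect_identical(nrow(tr$points), as.integer(360 / step))
  }
  expect_error(trace_settings(step_deg = 7), "divide")
  expect_error(trace_settings(roi_size = 20), "odd")
})

test_that("tracing a blank frame fails at step 0 with a diagnostic", {
  blank <- image_frame(matrix(5, 512, 512), 0.1)
  expect_error(trace_contour(blank, x_seed = c(355, 255), x0 = c(255, 255)),
               "step angle 0")
})

test_that("trace is equivariant under whole-pixel translation and 90-degree rotation", {
  sdk0 <- curvature_profile(trace_of(mode2_shape(0.08)))$sdk
  # translate the contour by whole pixels
  shp_t <- make_contour(10, list(c(2, 0.08, 0)), center = c(25.5 + 1.2, 25.5 - 0.7))
  img_t <- render_guv_slice(shp_t, optics_model(), noise = NULL)
  tr_t <- trace_contour(img_t, x_seed = c(255 + 12 + 108, 255 - 7))
  expect_lt(abs(curvature_profile(tr_t)$sdk - sdk0), 0.002)
  # rotate the image by 90 degrees (transpose + flip)
  img0 <- render_guv_slice(mode2_shape(0.08), optics_model(), noise = NULL)
  rot <- image_frame(t(img0$pixels)[, nrow(img0$pixels):1], img0$pixel_size)
  # this 90-degree rotation maps pixel (x, y) to (511 - y, x)
  tr_r <- trace_contour(rot, x_seed = c(511 - 255, 363))
  expect_lt(abs(curvature_profile(tr_r)$sdk - sdk0), 0.002)
})

test_that("SD_k stays below 0.005 for noiseless circles of radius 30-200 px", {
  for (Rpx in c(30, 60, 120, 200)) {
    shp <- make_contour(Rpx * 0.1, center = c(25.55, 25.55))
    tr <- trace_of(shp)
    expect_lt(curvature_profile(tr)$sdk, 0.005)
  }
})

test_that("pipeline SD_k matches the analytic oracle within 5% (or 0.002 absolute)", {
  shapes <- c(lapply(c(0.02, 0.08, 0.15), mode2_shape),
              list(make_contour(10, list(c(3, 0.05, 0.4)), center = c(25.5, 25.5)),
                   make_contour(10, list(c(2, 0.06, 0.2), c(3, 0.04, 1.1)),
                                center = c(25.5, 25.5))))
  for (shp in shapes) {
    sdk <- curvature_profile(trace_of(shp))$sdk
    truth <- contour_sdk(shp)$sdk
    expect_true(abs(sdk - truth) <= max(0.05 * truth, 0.002),
                label = sprintf("sdk %.5f vs truth %.5f", sdk, truth))
  }
})

test_that("SD_k increases strictly with single-mode amplitude", {
  sdk <- vapply(c(0.02, 0.05, 0.10, 0.15),
                function(a) curvature_profile(trace_of(mode2_shape(a)))$sdk,
                numeric(1))
  expect_true(all(diff(sdk) > 0))
})

test_that("trace wandering beyond 3x the initial radius is detected", {
  # seed the tracer on a tiny inner blob so the ROI keeps locking onto the
  # far-away ring: radius jumps beyond 3x the initial distance
  img2 <- std_image
  expect_error(trace_contour(img2, x_seed = c(265, 255), x0 = c(255, 255)),
               "3x|wandered|threshold")
})
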