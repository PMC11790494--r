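#' Optics and noise models for the synthetic confocal generator
#'
#' `optics_model()` describes how an equatorial GUV slice maps to pixel
#' intensities: a thin membrane ring rendered as a Gaussian profile of the
#' distance to the contour (emulating confocal blur of the labelled-lipid
#' channel), flat interior/exterior levels for a soluble dye channel, and a
#' constant background. `noise_model()` describes the confocal noise applied
#' afterwards: Poisson shot noise (at `poisson_gain` photons per intensity
#' unit) followed by additive Gaussian read noise; either component can be
#' disabled by setting it to 0.
#'
#' @param pixel_size physical pixel size, micrometres per pixel.
#' @param membrane_sigma Gaussian cross-section width of the ring signal
#'   (micrometres).
#' @param membrane_peak peak added intensity of the ring.
#' @param interior_level,exterior_level flat dye levels inside/outside the
#'   contour (intensity units).
#' @param background constant offset added everywhere.
#' @return an `optics_model` / `noise_model` list.
#' @export
optics_model <- function(pixel_size = 0.1, membrane_sigma = 0.2,
                         membrane_peak = 200, interior_level = 0,
                         exterior_level = 0, background = 10) {
  check_scalar_pos(pixel_size, "pixel_size")
  check_scalar_pos(membrane_sigma, "membrane_sigma")
  for (nm in c("membrane_peak", "interior_level", "exterior_level", "background"))
    check_scalar_pos(get(nm), nm, strict = FALSE)
  structure(list(pixel_size = pixel_size, membrane_sigma = membrane_sigma,
                 membrane_peak = membrane_peak, interior_level = interior_level,
                 exterior_level = exterior_level, background = background),
            class = "optics_model")
}

#' @param poisson_gain photons per intensity unit (0 disables shot noise).
#' @param gaussian_sd standard deviation of additive read noise (0 disables).
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   images.
#' @rdname optics_model
#' @export
noise_model <- function(poisson_gain = 1, gaussian_sd = 2, seed = 1L) {
  check_scalar_pos(poisson_gain, "poisson_gain", strict = FALSE)
  check_scalar_pos(gaussian_sd, "gaussian_sd", strict = FALSE)
  structure(list(poisson_gain = poisson_gain, gaussian_sd = gaussian_sd,
                 seed = as.integer(seed)), class = "noise_model")
}

#' Construct an image frame
#'
#' The atomic unit consumed by the tracing and flux modules: a 2D intensity
#' grid plus its physical pixel size. Pixel centres sit at 0-based integer
#' coordinates `(row, col)` scaled by `pixel_size`; i.e. the physical position
#' of pixel `[i, j]` (0-based) is `(x, y) = (j, i) * pixel_size` micrometres.
#'
#' @param pixels numeric matrix (rows x cols) of non-negative intensities;
#'   both dimensions must be at least 64.
#' @param pixel_size micrometres per pixel.
#' @param channel free-form channel label.
#' @param time acquisition time (minutes), optional.
#' @return an object of class `guv_frame`.
#' @export
image_frame <- function(pixels, pixel_size, channel = "unnamed", time = NA_real_) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_bad_arg("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 64L || ncol(pixels) < 64L)
    stop_bad_arg("frame must be at least 64 x 64 pixels")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop_bad_arg("pixel intensities must be finite and non-negative")
  check_scalar_pos(pixel_size, "pixel_size")
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 channel = channel, time = time), class = "guv_frame")
}

#' @export
print.guv_frame <- function(x, ...) {
  cat(sprintf("guv_frame: %d x %d px @ %.3g um/px, channel '%s'%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$channel,
              if (is.finite(x$time)) sprintf(", t = %g min", x$time) else ""))
  invisible(x)
}

# Signed radial position of pixels relative to a star-shaped contour, plus the
# (unsigned) distance to a dense polyline sampling of the contour, computed
# only inside a band around the ring (membrane intensity is negligible
# elsewhere). The polyline is sampled every 0.1 degrees, much finer than a
# pixel, so nearest-vertex distance is exact at sub-pixel scale.
contour_distance_field <- function(shape, pixel_size, size, band_um) {
  idx <- seq_len(size) - 1L
  px <- matrix(rep(idx, each = size), size, size)   # x = col (0-based)
  py <- matrix(rep(idx, times = size), size, size)  # y = row
  x <- px * pixel_size - shape$center[1]
  y <- py * pixel_size - shape$center[2]
  rho <- sqrt(x^2 + y^2)
  theta <- atan2(y, x) %% (2 * pi)
  rtheta <- matrix(contour_radius(shape, as.numeric(theta)), size, size)
  inside <- rho < rtheta
  dist <- abs(rho - rtheta)  # first-order distance; refined inside the band

  band <- which(dist < band_um)
  if (length(band)) {
    poly <- contour_points(shape, step_deg = 0.1)
    th_poly <- attr(poly, "theta")
    dth <- th_poly[2] - th_poly[1]
    npoly <- nrow(poly)
    win <- 120L  # +/- 12 degrees of candidate polyline vertices
    qx <- (px[band]) * pixel_size
    qy <- (py[band]) * pixel_size
    i0 <- as.integer(round(theta[band] / dth))
    chunk <- 4000L
    for (s in seq(1L, length(band), by = chunk)) {
      e <- min(s + chunk - 1L, length(band))
      sel <- s:e
      cand <- outer(i0[sel], -win:win, "+") %% npoly + 1L
      dx <- matrix(poly[cand, 1], length(sel)) - qx[sel]
      dy <- matrix(poly[cand, 2], length(sel)) - qy[sel]
      dist[band[sel]] <- sqrt(do.call(pmin, as.data.frame(dx^2 + dy^2)))
    }
  }
  list(inside = inside, dist = dist)
}

#' Render a synthetic equatorial GUV slice
#'
#' Produces a confocal-style image of a GUV contour: every pixel receives
#' `background`, plus `interior_level` or `exterior_level` according to a
#' point-in-contour test, plus a membrane ridge
#' `membrane_peak * exp(-d^2 / (2 sigma^2))` where `d` is the distance from
#' the pixel centre to the contour. Optional Poisson-then-Gaussian noise is
#' applied last; a fixed noise seed gives a bit-identical frame.
#'
#' @param shape a [make_contour()] object.
#' @param optics an [optics_model()].
#' @param noise a [noise_model()], or `NULL` for a noiseless render.
#' @param size frame side length in pixels (default 512).
#' @param channel,time passed to [image_frame()].
#' @return a [image_frame()] of `size` x `size` pixels.
#' @examples
#' img <- render_guv_slice(make_contour(10), optics_model(), noise = NULL)
#' range(img$pixels)
#' @export
render_guv_slice <- function(shape, optics = optics_model(), noise = NULL,
                             size = 512L, channel = "membrane", time = NA_real_) {
  stopifnot(inherits(shape, "guv_contour"), inherits(optics, "optics_model"))
  size <- as.integer(size)
  ps <- optics$pixel_size
  margin <- 5 * ps
  ext <- range(contour_points(shape, 0.5))
  lims <- c(0, (size - 1) * ps)
  poly <- contour_points(shape, 0.5)
  if (min(poly) < lims[1] + margin || max(poly) > lims[2] - margin) {
    need <- ceiling((max(abs(range(poly))) + margin) / ps) + 1
    stop_bad_arg("contour exceeds the frame (with a 5 px margin); ",
                 "need a frame of at least ", need, " px at this pixel size")
  }
  fld <- contour_distance_field(shape, ps, size,
                                band_um = 6 * optics$membrane_sigma + ps)
  pix <- optics$background +
    ifelse(fld$inside, optics$interior_level, optics$exterior_level) +
    optics$membrane_peak * exp(-fld$dist^2 / (2 * optics$membrane_sigma^2))
  if (!is.null(noise)) pix <- apply_noise(pix, noise)
  image_frame(pix, ps, channel = channel, time = time)
}

apply_noise <- function(pix, noise) {
  stopifnot(inherits(noise, "noise_model"))
  with_rng_seed(noise$seed, {
    if (noise$poisson_gain > 0)
      pix[] <- rpois(length(pix), pix * noise$poisson_gain) / noise$poisson_gain
    if (noise$gaussian_sd > 0)
      pix[] <- pix + rnorm(length(pix), 0, noise$gaussian_sd)
    pix[pix < 0] <- 0
    pix
  })
}
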