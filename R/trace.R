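#' Tracer settings
#'
#' Parameters of the iterative rotation-stepping membrane tracer. The
#' defaults correspond to the standard analysis of 512 x 512 px confocal GUV
#' slices: a 21 px region of interest, 3 degree rotation steps (120 points per
#' trace) and an adaptive threshold computed as the mean intensity of a square
#' region of side `d = |x_seed - x0| + extra` pixels centred on the vesicle
#' centre of mass.
#'
#' @param roi_size side of the square ROI in pixels; odd, between 5 and 101.
#' @param step_deg rotation step in degrees; must divide 360.
#' @param extra pixels added to the seed-to-centre distance when sizing the
#'   threshold region (default 20).
#' @param max_points safety cap on the number of trace points.
#' @return a `trace_settings` list.
#' @export
trace_settings <- function(roi_size = 21L, step_deg = 3, extra = 20, max_points = 1000L) {
  roi_size <- as.integer(roi_size)
  if (roi_size < 5L || roi_size > 101L || roi_size %% 2L == 0L)
    stop_bad_arg("`roi_size` must be odd and within [5, 101]")
  if (360 %% step_deg != 0) stop_bad_arg("`step_deg` must divide 360")
  check_scalar_pos(extra, "extra", strict = FALSE)
  structure(list(roi_size = roi_size, step_deg = step_deg, extra = extra,
                 max_points = as.integer(max_points)), class = "trace_settings")
}

#' Adaptive membrane intensity threshold
#'
#' Mean intensity of a square region centred on the vesicle centre of mass
#' `x0` and extending `d = |x_seed - x0| + extra` pixels from it in each
#' direction (clipped to the frame). Since `|x_seed - x0|` is the vesicle
#' radius at the seed, the region covers the whole vesicle -- interior,
#' membrane ring and an `extra`-pixel margin -- so its mean lies strictly
#' between the background and the ring peak and adapts to GUV size. Membrane
#' pixels are those with intensity strictly above this value.
#'
#' @param image a [image_frame()].
#' @param x0 centre of mass, `c(x, y)` in 0-based pixel coordinates
#'   (x = column, y = row).
#' @param x_seed current membrane seed point, same coordinates.
#' @param extra pixels added to the seed-centre distance (default 20).
#' @return the scalar intensity threshold.
#' @export
adaptive_threshold <- function(image, x0, x_seed, extra = 20) {
  stopifnot(inherits(image, "guv_frame"))
  pix <- image$pixels
  for (p in list(x0, x_seed)) {
    if (length(p) != 2L || any(p < 0) || p[1] > ncol(pix) - 1 || p[2] > nrow(pix) - 1)
      stop_bad_arg("`x0` and `x_seed` must lie inside the frame")
  }
  d <- sqrt(sum((x_seed - x0)^2)) + extra
  if (d < 3) stop_bad_arg("threshold region is degenerate (extent < 3 px)")
  cols <- max(0, round(x0[1] - d)):min(ncol(pix) - 1, round(x0[1] + d))
  rows <- max(0, round(x0[2] - d)):min(nrow(pix) - 1, round(x0[2] + d))
  mean(pix[rows + 1L, cols + 1L])
}

# Otsu's histogram threshold (256 bins); used only for the default
# centre-of-mass estimate.
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- as.numeric(tabulate(pmin(256L, 1L + floor((v - rng[1]) / diff(rng) * 256)), 256L))
  w <- cumsum(h); m <- cumsum(h * seq_len(256L))
  mt <- m[256L]; n <- w[256L]
  between <- (mt * w - m * n)^2 / (w * (n - w))
  between[!is.finite(between)] <- 0
  k <- which.max(between)
  rng[1] + k / 256 * diff(rng)
}

#' Estimate the vesicle centre of mass
#'
#' Intensity-weighted centroid of the pixels above an Otsu threshold. The
#' experimentalist's manual centre selection can be reproduced by passing an
#' explicit `x0` to [trace_contour()] instead.
#'
#' @param image a [image_frame()].
#' @return `c(x, y)` in 0-based pixel coordinates.
#' @export
estimate_center <- function(image) {
  stopifnot(inherits(image, "guv_frame"))
  pix <- image$pixels
  thr <- otsu_threshold(as.numeric(pix))
  sel <- which(pix > thr, arr.ind = TRUE)
  if (nrow(sel) == 0) sel <- which(pix >= thr, arr.ind = TRUE)
  w <- pix[sel]
  c(x = sum((sel[, 2] - 1) * w) / sum(w),
    y = sum((sel[, 1] - 1) * w) / sum(w))
}

#' Trace the membrane contour of an equatorial GUV slice
#'
#' Implements the automated rotation-stepping tracer. Starting from a seed
#' pixel on the membrane, at each step the pixels of a square ROI around the
#' current seed with intensity above the adaptive threshold are rotated into a
#' local frame in which the membrane is approximately horizontal (the frame is
#' aligned with the seed's polar angle about the centre `x0`, which keeps the
#' parabola fit well-posed at every angle), a second-order polynomial
#' `y(x) = a + b x + c x^2` is fitted through their coordinates, and the
#' membrane point is taken at the parabola vertex. The thresholded ROI pixel
#' closest to the vertex (ties broken by higher intensity, then lower row,
#' then lower column) is recorded as the membrane pixel; the next seed is
#' obtained by rotating the membrane point about `x0` by `step_deg`. The
#' rotation is carried out on the exact angular grid `alpha_0 + i * step_deg`
#' (taking the radius from the refined point), so the trace samples the
#' contour at exactly `360 / step_deg` uniformly spaced polar angles and
#' sub-pixel tangential noise in the vertex cannot accumulate into angular
#' drift. Iterating from 0 to 360 degrees yields `360 / step_deg` ordered
#' points.
#'
#' Both the snapped membrane pixels and the sub-pixel vertices are stored;
#' downstream curvature analysis uses the sub-pixel vertices by default, which
#' removes the ~0.3 px quantisation noise of pixel snapping (see
#' [curvature_profile()]).
#'
#' @param image a [image_frame()].
#' @param x_seed starting membrane point, `c(x, y)` 0-based pixel coordinates.
#' @param x0 vesicle centre of mass; defaults to [estimate_center()].
#' @param settings a [trace_settings()].
#' @param rotate_refined logical; if `TRUE` (default) the next seed takes its
#'   radius from the refined membrane point (the trace tracks deformed
#'   contours radially), if `FALSE` from the un-refined current seed (a pure
#'   rotation of the starting point, the literal reading of the stepping
#'   rule).
#' @param weight_fit logical; if `TRUE` (default) the parabola fit is weighted
#'   by each pixel's intensity excess above the threshold, which centres the
#'   fit on the ridge; `FALSE` gives the plain unweighted coordinate fit.
#' @return an object of class `guv_trace` with fields `points` (n x 2 matrix
#'   of membrane pixels), `vertices` (n x 2 sub-pixel vertices), `origin`,
#'   `step_deg`, `fits` (per-step polynomial coefficients).
#' @examples
#' img <- render_guv_slice(make_contour(10), optics_model(), noise = NULL)
#' tr <- trace_contour(img, x_seed = c(355, 255))
#' nrow(tr$points)  # 120 points at 3 degree steps
#' @export
trace_contour <- function(image, x_seed, x0 = NULL,
                          settings = trace_settings(), rotate_refined = TRUE,
                          weight_fit = TRUE) {
  stopifnot(inherits(image, "guv_frame"), inherits(settings, "trace_settings"))
  pix <- image$pixels
  W <- ncol(pix); H <- nrow(pix)
  if (is.null(x0)) x0 <- estimate_center(image)
  x0 <- as.numeric(x0); x_seed <- as.numeric(x_seed)
  n_steps <- as.integer(360 / settings$step_deg)
  if (n_steps > settings$max_points)
    stop_bad_arg("360/step_deg exceeds `max_points`")
  half <- (settings$roi_size - 1L) %/% 2L
  phi <- settings$step_deg * pi / 180
  r_init <- sqrt(sum((x_seed - x0)^2))
  if (r_init == 0) stop_bad_arg("`x_seed` coincides with `x0`")
  alpha0 <- atan2(x_seed[2] - x0[2], x_seed[1] - x0[1])

  pts <- verts <- matrix(NA_real_, n_steps, 2,
                         dimnames = list(NULL, c("x", "y")))
  fits <- matrix(NA_real_, n_steps, 3, dimnames = list(NULL, c("a", "b", "c")))
  seed_cur <- x_seed

  for (i in seq_len(n_steps)) {
    ang_deg <- (i - 1L) * settings$step_deg
    thr <- adaptive_threshold(image, x0, seed_cur, settings$extra)
    cx <- round(seed_cur[1]); cy <- round(seed_cur[2])
    cols <- max(0, cx - half):min(W - 1L, cx + half)
    rows <- max(0, cy - half):min(H - 1L, cy + half)
    sub <- pix[rows + 1L, cols + 1L, drop = FALSE]
    sel <- which(sub > thr, arr.ind = TRUE)
    if (nrow(sel)) {
      # keep the disc inscribed in the ROI square: a rotation-invariant
      # window cannot clip the membrane band asymmetrically at its corners,
      # which would bias the parabola fit at diagonal polar angles
      rx <- cols[sel[, 2]]; ry <- rows[sel[, 1]]   # 0-based pixel coords
      keep <- (rx - seed_cur[1])^2 + (ry - seed_cur[2])^2 <= half^2
      sel <- sel[keep, , drop = FALSE]
      rx <- rx[keep]; ry <- ry[keep]
    }
    if (nrow(sel) == 0)
      stop_bad_arg("trace failed at step angle ", ang_deg,
                   " deg: no ROI pixels above the adaptive threshold")
    rint <- sub[sel]

    alpha <- alpha0 + (i - 1L) * phi
    er <- c(cos(alpha), sin(alpha)); et <- c(-sin(alpha), cos(alpha))
    ux <- rx - seed_cur[1]; uy <- ry - seed_cur[2]
    xt <- ux * et[1] + uy * et[2]
    yt <- ux * er[1] + uy * er[2]

    vx <- 0; vy <- mean(yt); cf <- c(mean(yt), 0, 0)
    if (length(unique(round(xt, 9))) >= 3L) {
      # weighting by the above-threshold intensity excess concentrates the fit
      # on the ridge centre and suppresses band-edge quantisation noise
      wts <- if (weight_fit) rint - thr else rep(1, length(xt))
      X <- cbind(1, xt, xt^2)
      cf <- tryCatch(as.numeric(solve(crossprod(X, X * wts),
                                      crossprod(X, yt * wts))),
                     error = function(e) rep(NA_real_, 3))
      if (all(is.finite(cf)) && abs(cf[3]) > 1e-12) {
        vx <- -cf[2] / (2 * cf[3])
        if (abs(vx) > settings$roi_size) vx <- 0  # runaway vertex: stay on the ray
        vy <- cf[1] + cf[2] * vx + cf[3] * vx^2
      } else if (all(is.finite(cf))) {
        vx <- 0; vy <- cf[1]
      } else {
        cf <- c(mean(yt), 0, 0); vx <- 0; vy <- cf[1]
      }
    }
    vertex <- seed_cur + vx * et + vy * er

    d2 <- (rx - vertex[1])^2 + (ry - vertex[2])^2
    ord <- order(round(d2, 9), -rint, ry, rx)[1]
    pt <- c(rx[ord], ry[ord])

    if (sqrt(sum((pt - x0)^2)) > 3 * r_init)
      stop_bad_arg("trace wandered at step angle ", ang_deg,
                   " deg: point left 3x the initial radius")

    pts[i, ] <- pt
    verts[i, ] <- vertex
    fits[i, ] <- cf
    r_next <- if (rotate_refined) sqrt(sum((pt - x0)^2)) else
      sqrt(sum((seed_cur - x0)^2))
    seed_cur <- x0 + r_next * c(cos(alpha + phi), sin(alpha + phi))
  }

  structure(list(points = pts, vertices = verts, origin = x0,
                 step_deg = settings$step_deg, settings = settings,
                 fits = fits), class = "guv_trace")
}

#' Extract membrane point coordinates from a trace
#'
#' @param trace a [trace_contour()] result.
#' @param use `"vertex"` for sub-pixel parabola vertices (default) or
#'   `"pixel"` for the snapped membrane pixels.
#' @return an n x 2 matrix of (x, y) pixel coordinates.
#' @export
trace_points <- function(trace, use = c("vertex", "pixel")) {
  stopifnot(inherits(trace, "guv_trace"))
  switch(match.arg(use), vertex = trace$vertices, pixel = trace$points)
}

#' @export
print.guv_trace <- function(x, ...) {
  cat(sprintf("GUV trace: %d points, %g deg steps, origin (%.1f, %.1f)\n",
              nrow(x$points), x$step_deg, x$origin[1], x$origin[2]))
  invisible(x)
}
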