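#' Cargo flux series
#'
#' Time series of interior and exterior dye intensities and the derived
#' relative import level
#' \deqn{\mathrm{import} = \frac{\langle I_{out}\rangle - \langle I_{in}\rangle}{\langle I_{out}\rangle},}
#' the cargo-influx statistic: 1 for fully excluded cargo, 0 at full
#' equilibration.
#'
#' @param times frame times, minutes.
#' @param I_in mean interior intensities.
#' @param I_out mean exterior intensities (must be positive).
#' @return a data frame of class `flux_series` with an extra `import` column.
#' @export
flux_series <- function(times, I_in, I_out) {
  n <- length(times)
  if (length(I_in) != n || length(I_out) != n)
    stop_bad_arg("`times`, `I_in`, `I_out` must match in length")
  if (any(I_out <= 0)) stop_bad_arg("exterior intensity must be positive")
  structure(data.frame(time = times, I_in = I_in, I_out = I_out,
                       import = (I_out - I_in) / I_out),
            class = c("flux_series", "data.frame"))
}

roi_mean <- function(pix, center, side) {
  half <- (side - 1) / 2
  cols <- round(center[1] - half):round(center[1] + half)
  rows <- round(center[2] - half):round(center[2] + half)
  if (min(cols) < 0 || min(rows) < 0 || max(cols) > ncol(pix) - 1 ||
      max(rows) > nrow(pix) - 1)
    stop_bad_arg("ROI at (", center[1], ", ", center[2], ") of side ", side,
                 " px falls outside the frame")
  mean(pix[rows + 1L, cols + 1L])
}

#' Relative import level from a cargo-channel time-lapse
#'
#' For each frame, the mean intensity of a square interior ROI centred in the
#' vesicle is compared with the mean of two square exterior (background) ROIs:
#' the relative import level is `(I_out - I_in) / I_out` with `I_out` the mean
#' of the two exterior ROI means. By default the exterior ROIs sit in the two
#' frame corners farthest from the vesicle centre; positions can be overridden.
#'
#' @param frames list of [image_frame()] (one per time point).
#' @param center vesicle centre `c(x, y)`, 0-based pixels; default estimated
#'   from the first frame.
#' @param roi_in interior ROI side, pixels (default 30).
#' @param roi_out exterior ROI side, pixels (default 50).
#' @param out_positions optional list of two `c(x, y)` exterior ROI centres.
#' @param contour optional [make_contour()] object describing the vesicle; if
#'   supplied, exterior ROIs overlapping the vesicle raise an error.
#' @param combine how the two exterior ROIs are combined: `"mean_of_means"`
#'   (default) or `"pooled"` (single mean over all exterior pixels).
#' @return a [flux_series()], one row per frame (times from the frames).
#' @examples
#' shp <- make_contour(10, center = c(25.5, 25.5))
#' opt <- optics_model(interior_level = 10, exterior_level = 100,
#'                     membrane_peak = 150, background = 0)
#' st <- simulate_influx_stack(shp, opt, permeability_scenario(0), times = c(0, 5))
#' flux_statistic(st$frames, center = c(255, 255))
#' @export
flux_statistic <- function(frames, center = NULL, roi_in = 30, roi_out = 50,
                           out_positions = NULL, contour = NULL,
                           combine = c("mean_of_means", "pooled")) {
  combine <- match.arg(combine)
  if (!length(frames)) stop_bad_arg("`frames` must contain at least one frame")
  stopifnot(all(vapply(frames, inherits, logical(1), what = "guv_frame")))
  pix1 <- frames[[1]]$pixels
  H <- nrow(pix1); W <- ncol(pix1)
  if (is.null(center)) center <- estimate_center(frames[[1]])
  if (is.null(out_positions)) {
    m <- roi_out / 2 + 2
    corners <- list(c(m, m), c(W - 1 - m, m), c(m, H - 1 - m),
                    c(W - 1 - m, H - 1 - m))
    d <- vapply(corners, function(p) sum((p - center)^2), numeric(1))
    out_positions <- corners[order(d, decreasing = TRUE)][1:2]
  }
  if (length(out_positions) != 2L)
    stop_bad_arg("exactly two exterior ROI positions are required")
  if (!is.null(contour)) {
    stopifnot(inherits(contour, "guv_contour"))
    ps <- frames[[1]]$pixel_size
    for (p in out_positions) {
      cor_xy <- expand.grid(x = c(-1, 1) * roi_out / 2 + p[1],
                            y = c(-1, 1) * roi_out / 2 + p[2])
      rel <- cbind(cor_xy$x * ps - contour$center[1],
                   cor_xy$y * ps - contour$center[2])
      rho <- sqrt(rowSums(rel^2))
      rmax <- contour_radius(contour, atan2(rel[, 2], rel[, 1]))
      if (any(rho < rmax))
        stop_bad_arg("exterior ROI at (", p[1], ", ", p[2],
                     ") overlaps the vesicle contour")
    }
  }
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (anyNA(times)) times <- seq_along(frames) - 1
  I_in <- I_out <- numeric(length(frames))
  for (i in seq_along(frames)) {
    pix <- frames[[i]]$pixels
    I_in[i] <- roi_mean(pix, center, roi_in)
    m1 <- roi_mean(pix, out_positions[[1]], roi_out)
    m2 <- roi_mean(pix, out_positions[[2]], roi_out)
    I_out[i] <- if (combine == "mean_of_means") (m1 + m2) / 2 else {
      # pooled: both ROIs have equal pixel counts, so this equals the mean of
      # all exterior pixels
      (m1 + m2) / 2
    }
  }
  flux_series(times, I_in, I_out)
}

#' FRAP recovery analysis of the vesicle interior
#'
#' Quantifies fluorescence recovery after photobleaching of the vesicle lumen
#' as a binary open/sealed channel readout. The recovery fraction at the
#' analysis horizon is
#' `(I_end - I_postbleach) / (I_prebleach - I_postbleach)`; the vesicle is
#' called `recovered` when the fraction exceeds `cutoff`.
#'
#' @param series a [flux_series()] covering the bleach event.
#' @param bleach_time time of the bleach, minutes; must fall strictly inside
#'   the series with at least 3 later points.
#' @param horizon analysis horizon, minutes after the bleach (default 40).
#' @param cutoff recovery-fraction cutoff for the boolean readout
#'   (default 0.2).
#' @return list of class `frap_result`: `recovery_fraction`, `recovered`,
#'   `I_prebleach`, `I_postbleach`, `I_end`, `bleach_time`, `horizon`.
#' @export
frap_analysis <- function(series, bleach_time, horizon = 40, cutoff = 0.2) {
  stopifnot(inherits(series, "flux_series"))
  check_scalar_pos(horizon, "horizon")
  pre <- series$time < bleach_time
  post <- series$time >= bleach_time
  if (!any(pre) || sum(post) < 3L)
    stop_bad_arg("bleach time must lie inside the series with >= 3 post-bleach points")
  I_pre <- series$I_in[max(which(pre))]
  I_post <- series$I_in[which(post)[1]]
  if (I_pre - I_post < 0.1 * I_pre)
    stop_bad_arg("no detectable bleach event: post-bleach drop < 10% of pre-bleach level")
  in_h <- series$time >= bleach_time & series$time <= bleach_time + horizon
  I_end <- series$I_in[max(which(in_h))]
  frac <- (I_end - I_post) / (I_pre - I_post)
  if (frac < -0.5 || frac > 1.5)
    warning("recovery fraction outside the [-0.5, 1.5] sanity band")
  structure(list(recovery_fraction = frac, recovered = frac > cutoff,
                 I_prebleach = I_pre, I_postbleach = I_post, I_end = I_end,
                 bleach_time = bleach_time, horizon = horizon, cutoff = cutoff),
            class = "frap_result")
}

#' @export
print.frap_result <- function(x, ...) {
  cat(sprintf("FRAP: recovery fraction %.3f at %g min horizon -> %s\n",
              x$recovery_fraction, x$horizon,
              if (x$recovered) "recovered (channels open)" else "no recovery (sealed)"))
  invisible(x)
}

#' Molecular-weight cut-off summary of cargo import
#'
#' Summarises relative import levels measured for a ladder of cargo probes of
#' increasing molecular weight: per-probe mean, standard error of the mean and
#' sample size, plus the bracketing pair of molecular weights between which
#' the mean import level first reaches 0.5 (the partial-permeability
#' midpoint, where half of the cargo is excluded).
#'
#' @param per_probe named list: names are molecular weights in kDa, values are
#'   numeric vectors of per-GUV relative import levels. At least 2 probes.
#' @return list of class `cutoff_summary`: `table` (data frame `mw_kda`,
#'   `mean`, `sem`, `n`) sorted by molecular weight, and `bracket`
#'   (`c(low, high)` in kDa, or `NULL` when no probe reaches 0.5).
#' @examples
#' cutoff_summary(list(`20` = c(0.04, 0.06), `70` = c(0.45, 0.55),
#'                     `150` = c(0.9, 0.92)))
#' @export
cutoff_summary <- function(per_probe) {
  if (length(per_probe) < 2L) stop_bad_arg("need at least 2 probes")
  mw <- as.numeric(names(per_probe))
  if (anyNA(mw)) stop_bad_arg("probe names must be molecular weights in kDa")
  ord <- order(mw)
  mw <- mw[ord]; per_probe <- per_probe[ord]
  tab <- data.frame(
    mw_kda = mw,
    mean = vapply(per_probe, mean, numeric(1)),
    sem = vapply(per_probe, function(x)
      if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_, numeric(1)),
    n = vapply(per_probe, length, integer(1)),
    row.names = NULL)
  cross <- which(tab$mean >= 0.5)
  bracket <- if (length(cross) && min(cross) > 1L)
    c(low = mw[min(cross) - 1L], high = mw[min(cross)])
  else if (length(cross)) c(low = NA_real_, high = mw[min(cross)])
  else NULL
  structure(list(table = tab, bracket = bracket), class = "cutoff_summary")
}

#' @export
print.cutoff_summary <- function(x, ...) {
  print(x$table)
  if (is.null(x$bracket)) cat("no probe reaches the 50% import midpoint\n")
  else cat(sprintf("50%% import midpoint bracketed by %g and %g kDa\n",
                   x$bracket[["low"]], x$bracket[["high"]]))
  invisible(x)
}
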