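#' Normalized local curvature profile of a traced GUV
#'
#' Computes the per-point normalized local curvature
#' \deqn{k_i = R_0 / R_i,} where `R_0` is the radius of the least-squares
#' reference circle of the trace and `R_i` the distance of trace point `i`
#' from the fitted centre, then summarises the vesicle shape by `SD_k`, the
#' population standard deviation of all `k_i`. A vesicle is classified as
#' deformed when `SD_k` strictly exceeds the threshold; the default 0.026 is
#' the mean `SD_k` of a bare-GUV reference population, and can be recomputed
#' from a user-supplied bare set with [calibrate_baseline()].
#'
#' @param trace a [trace_contour()] result.
#' @param circle optional [fit_reference_circle()] result; by default fitted
#'   from this trace (it must come from the same trace).
#' @param threshold deformation threshold on `SD_k` (default 0.026).
#' @param use point representation: `"vertex"` (sub-pixel, default) or
#'   `"pixel"` (the snapped membrane pixels).
#' @return an object of class `guv_curvature`: `k` (per-point ratios), `R_i`,
#'   `R0`, `center`, `sdk`, `deformed`, `threshold`.
#' @examples
#' img <- render_guv_slice(make_contour(10), optics_model(), noise = NULL)
#' tr <- trace_contour(img, x_seed = c(355, 255))
#' curvature_profile(tr)$sdk   # ~0 for a circular vesicle
#' @export
curvature_profile <- function(trace, circle = NULL, threshold = 0.026,
                              use = c("vertex", "pixel")) {
  use <- match.arg(use)
  p <- trace_points(trace, use)
  if (is.null(circle)) circle <- fit_reference_circle(p)
  stopifnot(inherits(circle, "guv_circle"))
  check_scalar_pos(threshold, "threshold", strict = FALSE)
  ri <- sqrt((p[, 1] - circle$center[1])^2 + (p[, 2] - circle$center[2])^2)
  if (any(ri <= .Machine$double.eps))
    stop_bad_arg("a trace point coincides with the fitted centre (R_i = 0)")
  k <- circle$radius / ri
  sdk <- sd_pop(k)
  structure(list(k = k, R_i = ri, R0 = circle$radius, center = circle$center,
                 sdk = sdk, deformed = sdk > threshold, threshold = threshold),
            class = "guv_curvature")
}

#' @export
print.guv_curvature <- function(x, ...) {
  cat(sprintf("curvature profile: %d points, R0 = %.2f px, SD_k = %.4f (%s at %.3f)\n",
              length(x$k), x$R0, x$sdk,
              if (x$deformed) "deformed" else "undeformed", x$threshold))
  invisible(x)
}

#' Population shape statistics
#'
#' Pools per-GUV curvature profiles into a deformation efficiency (the
#' fraction of analysed vesicles classified deformed) and a pooled histogram
#' of all normalized local curvatures `k_i`.
#'
#' @param profiles list of [curvature_profile()] results.
#' @param bins histogram bin edges for the pooled `k_i` (extended
#'   automatically if values fall outside).
#' @return a list of class `guv_population`: `sdk` (per-GUV SD_k), `deformed`
#'   (logical), `efficiency`, `n`, `hist` (list with `breaks`, `counts`,
#'   `mids`), `k_pooled_sd`.
#' @export
population_stats <- function(profiles, bins = seq(0.5, 1.5, by = 0.02)) {
  if (!length(profiles)) stop_bad_arg("`profiles` must contain at least one profile")
  ok <- vapply(profiles, inherits, logical(1), what = "guv_curvature")
  if (!all(ok)) stop_bad_arg("all elements must be curvature profiles")
  sdk <- vapply(profiles, `[[`, numeric(1), "sdk")
  deformed <- vapply(profiles, `[[`, logical(1), "deformed")
  k <- unlist(lapply(profiles, `[[`, "k"), use.names = FALSE)
  if (min(k) < min(bins) || max(k) > max(bins)) {
    by <- diff(bins)[1]
    bins <- seq(by * floor(min(k, bins) / by), by * ceiling(max(k, bins) / by), by = by)
  }
  h <- graphics::hist(k, breaks = bins, plot = FALSE)
  list(sdk = sdk, deformed = deformed,
       efficiency = mean(deformed), n = length(profiles),
       hist = list(breaks = h$breaks, counts = h$counts, mids = h$mids),
       k_pooled_sd = sd_pop(k))
}

#' Calibrate the deformation threshold from a bare-GUV population
#'
#' Recomputes the deformation threshold as the mean `SD_k` of a user-supplied
#' set of undecorated (bare) vesicle profiles, mirroring how the reference
#' value 0.026 is obtained from a bare-GUV population.
#'
#' @param profiles list of [curvature_profile()] results from bare GUVs.
#' @return the calibrated threshold (mean SD_k).
#' @export
calibrate_baseline <- function(profiles) {
  if (!length(profiles)) stop_bad_arg("`profiles` must contain at least one profile")
  mean(vapply(profiles, `[[`, numeric(1), "sdk"))
}
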