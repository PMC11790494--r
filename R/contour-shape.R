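#' Analytic GUV contour shapes
#'
#' A `guv_contour` is the analytic ground truth standing in for the traced
#' outline of an equatorial GUV slice: a star-shaped closed curve defined in
#' polar form about its centre,
#' \deqn{r(\theta) = R \, (1 + \sum_n a_n \cos(n\theta + \phi_n)),}
#' with a base radius `R` (micrometres) perturbed by low-order cosine modes.
#' With an empty mode list the contour is an exact circle. The analytic form
#' provides the exact local-curvature statistic that the image-based tracer is
#' benchmarked against (see [contour_sdk()]).
#'
#' @param R base radius in micrometres; must be positive.
#' @param modes list of numeric triplets `c(order, amplitude, phase)`:
#'   integer mode order (>= 2), amplitude as a fraction of `R`, and phase in
#'   radians. The phase may be `NA`, in which case it is drawn uniformly on
#'   `[0, 2*pi)` using `seed`.
#' @param seed integer seed used only to draw `NA` phases; ignored otherwise.
#' @param center contour centre `c(x, y)` in micrometres.
#'
#' @details The total perturbation `sum(|amplitude|)` must stay below 0.5 so
#'   that `r(theta) > 0` everywhere and the curve cannot self-intersect.
#'
#' @return An object of class `guv_contour` with fields `center`, `R`,
#'   `modes` (a matrix with columns `order`, `amplitude`, `phase`).
#' @seealso [contour_radius()], [contour_points()], [contour_sdk()],
#'   [render_guv_slice()]
#' @examples
#' circ <- make_contour(10)                       # a 10 um circle
#' defm <- make_contour(10, list(c(2, 0.1, 0)))   # elliptical mode-2 shape
#' contour_sdk(defm)
#' @export
make_contour <- function(R, modes = list(), seed = NULL, center = c(0, 0)) {
  check_scalar_pos(R, "R")
  if (!is.list(modes)) stop_bad_arg("`modes` must be a list of c(order, amplitude, phase)")
  if (length(center) != 2L || !all(is.finite(center)))
    stop_bad_arg("`center` must be two finite coordinates")
  m <- if (length(modes)) do.call(rbind, lapply(modes, function(x) {
    if (length(x) == 2L) x <- c(x, NA_real_)
    if (length(x) != 3L) stop_bad_arg("each mode must be c(order, amplitude[, phase])")
    as.numeric(x)
  })) else matrix(numeric(0), 0, 3)
  colnames(m) <- c("order", "amplitude", "phase")
  if (nrow(m)) {
    if (any(m[, "order"] < 2) || any(m[, "order"] != round(m[, "order"])))
      stop_bad_arg("mode orders must be integers >= 2")
    if (sum(abs(m[, "amplitude"])) >= 0.5)
      stop_bad_arg("sum of |mode amplitudes| must be < 0.5 (self-intersection risk)")
    if (anyNA(m[, "phase"])) {
      na <- is.na(m[, "phase"])
      if (is.null(seed)) stop_bad_arg("`seed` required when mode phases are NA")
      m[na, "phase"] <- with_rng_seed(seed, runif(sum(na), 0, 2 * pi))
    }
  }
  structure(list(center = as.numeric(center), R = R, modes = m),
            class = "guv_contour")
}

#' Evaluate a contour's polar radius function
#'
#' @param shape a [make_contour()] object.
#' @param theta polar angles in radians (about the contour centre).
#' @return radii in micrometres, the same length as `theta`.
#' @export
contour_radius <- function(shape, theta) {
  stopifnot(inherits(shape, "guv_contour"))
  r <- rep(shape$R, length(theta))
  m <- shape$modes
  if (nrow(m)) for (i in seq_len(nrow(m)))
    r <- r + shape$R * m[i, "amplitude"] * cos(m[i, "order"] * theta + m[i, "phase"])
  r
}

#' Densely sample a contour as an (x, y) polyline
#'
#' @inheritParams contour_radius
#' @param step_deg angular sampling step in degrees (default 0.1, i.e. 3600
#'   points over the full turn).
#' @return a matrix with columns `x`, `y` (micrometres) and attribute
#'   `"theta"` holding the sampled angles.
#' @export
contour_points <- function(shape, step_deg = 0.1) {
  stopifnot(inherits(shape, "guv_contour"))
  check_scalar_pos(step_deg, "step_deg")
  theta <- seq(0, 2 * pi, by = step_deg * pi / 180)
  theta <- theta[theta < 2 * pi]
  r <- contour_radius(shape, theta)
  p <- cbind(x = shape$center[1] + r * cos(theta),
             y = shape$center[2] + r * sin(theta))
  attr(p, "theta") <- theta
  p
}

#' Analytic ground-truth curvature statistic of a contour
#'
#' Computes the deformation statistic SD_k of the analytic contour itself:
#' the curve is sampled on a dense angular grid, the least-squares reference
#' circle is fitted to the samples (the same Kasa fit used by the image
#' pipeline, so comparisons test tracing rather than circle conventions), the
#' normalized local curvatures `k_i = R0 / R_i` are formed from the distance
#' `R_i` of each sample to the fitted centre, and their population standard
#' deviation is returned.
#'
#' @inheritParams contour_points
#' @return a list with `sdk`, `R0`, `center` (fitted), `k` (per-sample
#'   curvature ratios).
#' @examples
#' contour_sdk(make_contour(10))$sdk                      # exactly 0
#' contour_sdk(make_contour(10, list(c(2, 0.1, 0))))$sdk  # > 0
#' @export
contour_sdk <- function(shape, step_deg = 0.1) {
  p <- contour_points(shape, step_deg)
  circ <- fit_reference_circle(p)
  ri <- sqrt((p[, 1] - circ$center[1])^2 + (p[, 2] - circ$center[2])^2)
  k <- circ$radius / ri
  list(sdk = sd_pop(k), R0 = circ$radius, center = circ$center, k = k)
}

#' @export
print.guv_contour <- function(x, ...) {
  cat("GUV contour: R =", x$R, "um, centre (", x$center[1], ",", x$center[2], ")\n")
  if (nrow(x$modes)) {
    cat("modes:\n")
    print(round(x$modes, 4))
  } else cat("unperturbed circle\n")
  invisible(x)
}
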