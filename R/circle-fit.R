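#' Least-squares reference circle (Kasa fit)
#'
#' Fits the algebraic least-squares circle through a set of points: the Kasa
#' formulation linearises \eqn{(x-a)^2 + (y-b)^2 = R_0^2} to
#' \eqn{x^2 + y^2 = 2ax + 2by + c} and solves the normal equations in closed
#' form. It is deterministic, non-iterative and exact when the points lie on
#' an exact circle. The fitted circle provides the reference radius `R0` and
#' centre from which normalized local curvatures are computed.
#'
#' @param points either a two-column matrix of point coordinates or a
#'   [trace_contour()] result (in which case the trace's membrane points are
#'   used, in the representation selected by `use`).
#' @param use for a trace input, which point representation to fit:
#'   `"vertex"` (sub-pixel parabola vertices, default) or `"pixel"` (snapped
#'   membrane pixels).
#' @return a list of class `guv_circle` with `center` (length 2) and
#'   `radius`, in the units of the input points.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 121)[-121]
#' fit_reference_circle(cbind(3 + 10 * cos(th), -2 + 10 * sin(th)))
#' @export
fit_reference_circle <- function(points, use = c("vertex", "pixel")) {
  if (inherits(points, "guv_trace")) points <- trace_points(points, match.arg(use))
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 3L)
    stop_bad_arg("circle fit needs a two-column matrix with >= 3 points")
  if (!all(is.finite(points))) stop_bad_arg("circle fit: points must be finite")
  x <- points[, 1]; y <- points[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  z <- x^2 + y^2
  sol <- tryCatch(qr.solve(crossprod(A), crossprod(A, z)),
                  error = function(e) NULL)
  if (is.null(sol))
    stop_bad_arg("circle fit failed: points are collinear or degenerate")
  a <- sol[1]; b <- sol[2]; cc <- sol[3]
  r2 <- cc + a^2 + b^2
  if (!is.finite(r2) || r2 <= 0)
    stop_bad_arg("circle fit failed: points are collinear or degenerate")
  structure(list(center = c(a, b), radius = sqrt(r2)), class = "guv_circle")
}

#' @export
print.guv_circle <- function(x, ...) {
  cat(sprintf("circle: centre (%.3f, %.3f), R0 = %.3f\n",
              x$center[1], x$center[2], x$radius))
  invisible(x)
}
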