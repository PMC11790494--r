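#' Raft-binding time series
#'
#' Integrated membrane intensity of labelled rafts as a function of time:
#' `times` in minutes (increasing) and the integrated intensity `I` of all
#' membrane pixels above the ROI-average threshold.
#'
#' @param times sampling times, minutes.
#' @param I integrated membrane intensities.
#' @return a data frame of class `binding_series`.
#' @export
binding_series <- function(times, I) {
  if (length(times) != length(I)) stop_bad_arg("`times` and `I` must match in length")
  if (any(diff(times) <= 0)) stop_bad_arg("`times` must be strictly increasing")
  if (!all(is.finite(I))) stop_bad_arg("intensities must be finite")
  structure(data.frame(time = times, I = I),
            class = c("binding_series", "data.frame"))
}

#' Fit classical target-binding kinetics
#'
#' Nonlinear least-squares fit of the saturating binding model
#' \deqn{I(t) = I_{max} \left(1 - e^{-a t}\right),}
#' where `I_max` is the plateau intensity and `a` the binding rate constant
#' (1/min). Starting values are `I_max = max(I)` and `a` from a log-linear
#' regression of the early, sub-plateau points; both parameters are kept
#' positive via log-parameterisation.
#'
#' @param series a [binding_series()] with at least 5 points.
#' @return object of class `binding_fit`: `I_max`, `a`, standard errors, the
#'   `(I_max, a)` covariance and the model function.
#' @examples
#' s <- generate_binding_series(100, 0.05, times = seq(2, 120, by = 4))
#' fit_binding(s)
#' @export
fit_binding <- function(series) {
  stopifnot(inherits(series, "binding_series"))
  if (nrow(series) < 5L) stop_bad_arg("binding fit needs at least 5 points")
  if (diff(range(series$I)) < 1e-12)
    stop_bad_arg("series is constant: cannot fit binding kinetics")
  imax0 <- max(series$I)
  early <- series$I > 0 & series$I < 0.95 * imax0 & series$time > 0
  a0 <- if (sum(early) >= 2) {
    z <- -log(pmax(1e-12, 1 - series$I[early] / (imax0 * 1.0001)))
    max(1e-6, unname(coef(lm(z ~ series$time[early] - 1))[1]))
  } else 1 / max(series$time)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      I ~ exp(lI) * (1 - exp(-exp(la) * time)), data = series,
      start = list(lI = log(imax0), la = log(a0)),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop_bad_arg("binding fit did not converge: ",
                                     conditionMessage(e),
                                     " (residual range ",
                                     paste(signif(range(series$I), 3), collapse = " to "),
                                     ")"))
  cf <- coef(fit)
  I_max <- exp(cf[["lI"]]); a <- exp(cf[["la"]])
  vc_log <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  J <- diag(c(I_max, a))
  vc <- J %*% vc_log %*% t(J)
  dimnames(vc) <- list(c("I_max", "a"), c("I_max", "a"))
  structure(list(I_max = I_max, a = a, se = sqrt(pmax(diag(vc), 0)), cov = vc,
                 model = function(t) I_max * (1 - exp(-a * t)), fit = fit),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("binding fit: I_max = %.4g (se %.2g), a = %.4g /min (se %.2g)\n",
              x$I_max, x$se[1], x$a, x$se[2]))
  invisible(x)
}

#' Integrated membrane intensity of a frame
#'
#' Support for binding-kinetics quantification on images: integrates all
#' pixel intensities above the average intensity of a square ROI centred on
#' the vesicle centre of mass, the same adaptive rule used by the tracer
#' threshold.
#'
#' @param image a [image_frame()].
#' @param x0 vesicle centre, 0-based `c(x, y)` pixels; default
#'   [estimate_center()].
#' @param width side of the averaging ROI in pixels (scales with GUV size).
#' @return the integrated above-threshold intensity (scalar).
#' @export
membrane_intensity <- function(image, x0 = NULL, width = 220) {
  stopifnot(inherits(image, "guv_frame"))
  if (is.null(x0)) x0 <- estimate_center(image)
  pix <- image$pixels
  half <- width / 2
  cols <- max(0, round(x0[1] - half)):min(ncol(pix) - 1, round(x0[1] + half))
  rows <- max(0, round(x0[2] - half)):min(nrow(pix) - 1, round(x0[2] + half))
  roi <- pix[rows + 1L, cols + 1L]
  sum(pix[pix > mean(roi)])
}
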