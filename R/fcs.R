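#' FCS autocorrelation curves
#'
#' Container for a fluorescence correlation spectroscopy curve: lag times
#' `tau` (seconds, positive, increasing) and autocorrelation amplitudes `G`,
#' with optional per-point weights (reciprocal-variance weights for the fit).
#'
#' @param tau lag times in seconds.
#' @param G autocorrelation values.
#' @param weights optional positive per-point weights.
#' @return a data frame of class `fcs_curve`.
#' @export
fcs_curve <- function(tau, G, weights = NULL) {
  if (length(tau) != length(G)) stop_bad_arg("`tau` and `G` must match in length")
  if (any(tau <= 0)) stop_bad_arg("lags must be positive")
  if (any(diff(tau) <= 0)) stop_bad_arg("lags must be strictly increasing")
  if (!all(is.finite(G))) stop_bad_arg("G values must be finite")
  out <- data.frame(tau = tau, G = G)
  if (!is.null(weights)) {
    if (length(weights) != length(tau) || any(weights <= 0))
      stop_bad_arg("`weights` must be positive and match the curve length")
    out$weight <- weights
  }
  class(out) <- c("fcs_curve", "data.frame")
  out
}

#' Fit the one-component 2D diffusion model to an FCS curve
#'
#' Weighted least-squares fit of
#' \deqn{G(\tau) = \frac{1}{N}\frac{1}{1 + \tau/\tau_D}}
#' by Levenberg-Marquardt on log-parameters (which keeps `N` and `tau_D`
#' positive throughout). `N` is the mean particle number in the 2D detection
#' area, `tau_D` the diffusion time; the model obeys `G(0) = 1/N` and
#' `G(tau_D) = 1/(2N)`. Starting values default to `N = 1/G` at the smallest
#' lag and `tau_D` at the half-amplitude lag.
#'
#' @param curve an [fcs_curve()] with at least 8 points whose lags span at
#'   least two decades.
#' @param init optional starting values `c(N, tau_D)`.
#' @return an object of class `fcs_fit`: `N`, `tau_D` (s), their standard
#'   errors, the 2 x 2 covariance of `(N, tau_D)`, and the model function.
#' @examples
#' cv <- generate_fcs_curve(10, 1e-3)
#' fit_fcs_2d(cv)
#' @export
fit_fcs_2d <- function(curve, init = NULL) {
  stopifnot(inherits(curve, "fcs_curve"))
  if (nrow(curve) < 8L)
    stop_bad_arg("FCS fit needs at least 8 points")
  if (log10(max(curve$tau) / min(curve$tau)) < 2)
    stop_bad_arg("FCS fit needs lags spanning at least two decades")
  if (diff(range(curve$G)) < 1e-12)
    stop_bad_arg("curve shows no decay (constant G): cannot fit")
  w <- if ("weight" %in% names(curve)) curve$weight else rep(1, nrow(curve))

  if (is.null(init)) {
    g0 <- max(curve$G[1], 1e-12)
    half <- curve$tau[which.min(abs(curve$G - g0 / 2))]
    init <- c(N = 1 / g0, tau_D = max(half, min(curve$tau)))
  }
  dat <- data.frame(tau = curve$tau, G = curve$G)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      G ~ exp(-lN) / (1 + tau / exp(lT)), data = dat, weights = w,
      start = list(lN = log(init[[1]]), lT = log(init[[2]])),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop_bad_arg("FCS fit did not converge: ",
                                     conditionMessage(e)))
  cf <- coef(fit)
  N <- exp(cf[["lN"]]); tau_D <- exp(cf[["lT"]])
  vc_log <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  J <- diag(c(N, tau_D))  # delta method from (log N, log tau_D)
  vc <- J %*% vc_log %*% t(J)
  dimnames(vc) <- list(c("N", "tau_D"), c("N", "tau_D"))
  structure(list(N = N, tau_D = tau_D,
                 se = sqrt(pmax(diag(vc), 0)),
                 cov = vc,
                 model = function(tau) (1 / N) / (1 + tau / tau_D),
                 fit = fit),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("2D diffusion FCS fit: N = %.4g (se %.2g), tau_D = %.4g s (se %.2g)\n",
              x$N, x$se[1], x$tau_D, x$se[2]))
  invisible(x)
}

#' Calibrate the detection-volume waist from a reference dye
#'
#' Fits the 2D diffusion model to a calibration curve measured on a dye of
#' known diffusion coefficient and inverts \eqn{\tau_D = r_0^2 / (4D)} to the
#' lateral waist radius \eqn{r_0 = \sqrt{4 D \tau_D}}. The fitted `tau_D`
#' uncertainty is propagated to `r0`.
#'
#' @param curve an [fcs_curve()] of the calibration dye.
#' @param D_known the dye's diffusion coefficient, um^2/s (e.g. 414 um^2/s
#'   for Atto488 in water at 25 C; supply a temperature-corrected value if
#'   working at another temperature).
#' @return list with `r0_nm`, `r0_se_nm`, `tau_D`, and the underlying
#'   [fit_fcs_2d()] result.
#' @examples
#' cal <- generate_fcs_curve(8, 25.875e-6)
#' calibrate_waist(cal, D_known = 414)$r0_nm  # ~207 nm
#' @export
calibrate_waist <- function(curve, D_known) {
  check_scalar_pos(D_known, "D_known")
  fit <- fit_fcs_2d(curve)
  r0_um <- sqrt(4 * D_known * fit$tau_D)
  se_um <- if (is.finite(fit$se[2])) r0_um * fit$se[2] / (2 * fit$tau_D) else NA_real_
  list(r0_nm = 1000 * r0_um, r0_se_nm = 1000 * se_um,
       tau_D = fit$tau_D, fit = fit)
}

#' Convert particle number to raft surface density and coverage
#'
#' The particle number `N` in the Gaussian detection area of waist `r0` gives
#' the surface density \eqn{\sigma = N / (\pi r_0^2)} (particles per um^2);
#' with the raft footprint `L x W` the surface coverage is
#' \eqn{\varphi = \sigma L W}. Defaults for `L`, `W` are the near-square raft
#' dimensions 70 x 55 nm; pass the elongated-state dimensions to evaluate that
#' conformation.
#'
#' @param N particle number in the detection area.
#' @param r0_nm detection-volume waist radius in nm.
#' @param L_nm,W_nm raft length and width in nm.
#' @return list of class `density_result`: `sigma_um2` (particles/um^2),
#'   `phi` (dimensionless coverage), and the inputs. Warns when `phi > 1`
#'   (unphysical coverage).
#' @examples
#' surface_density(8.07, r0_nm = 207)  # sigma ~ 60 um^-2, phi ~ 0.23
#' @export
surface_density <- function(N, r0_nm, L_nm = 70, W_nm = 55) {
  for (nm in c("N", "r0_nm", "L_nm", "W_nm")) check_scalar_pos(get(nm), nm)
  r0_um <- r0_nm / 1000
  sigma <- N / (pi * r0_um^2)
  phi <- sigma * (L_nm / 1000) * (W_nm / 1000)
  if (phi > 1) warning("surface coverage phi > 1: inputs are unphysical")
  structure(list(sigma_um2 = sigma, phi = phi, N = N, r0_nm = r0_nm,
                 L_nm = L_nm, W_nm = W_nm), class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("surface density: sigma = %.3g um^-2, coverage phi = %.3g (N = %.3g, r0 = %.3g nm)\n",
              x$sigma_um2, x$phi, x$N, x$r0_nm))
  invisible(x)
}
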