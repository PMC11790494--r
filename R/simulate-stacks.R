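#' Membrane permeability scenarios
#'
#' Describes how the interior soluble-dye level of a synthetic GUV evolves:
#' before `onset` nothing enters; from `onset` the interior level relaxes
#' exponentially towards the exterior level at `rate` (first-order
#' equilibration through open channels, 0 = non-permeable); optional bleach
#' events instantaneously multiply the interior level (FRAP emulation), after
#' which refilling continues at the same rate.
#'
#' @param rate equilibration rate constant, 1/min; 0 means non-permeable.
#' @param onset influx onset time, minutes.
#' @param bleaches list of `c(time_min, multiplier)` bleach events.
#' @return a `permeability_scenario` object.
#' @export
permeability_scenario <- function(rate = 0, onset = 0, bleaches = list()) {
  check_scalar_pos(rate, "rate", strict = FALSE)
  check_scalar_pos(onset, "onset", strict = FALSE)
  if (length(bleaches)) {
    bl <- do.call(rbind, lapply(bleaches, function(b) {
      if (length(b) != 2L || b[1] < 0 || b[2] < 0)
        stop_bad_arg("each bleach event must be c(time >= 0, multiplier >= 0)")
      as.numeric(b)
    }))
    bleaches <- bl[order(bl[, 1]), , drop = FALSE]
  } else bleaches <- matrix(numeric(0), 0, 2)
  colnames(bleaches) <- c("time", "multiplier")
  structure(list(rate = rate, onset = onset, bleaches = bleaches),
            class = "permeability_scenario")
}

# Exact piecewise solution of dI/dt = rate * (ext - I) for t >= onset, with
# instantaneous multiplicative bleach events. Reduces to
# ext * (1 - exp(-rate (t - onset))) for interior0 = 0 and no bleaching.
interior_level_at <- function(scenario, times, interior0, exterior) {
  events <- scenario$bleaches
  out <- numeric(length(times))
  for (j in seq_along(times)) {
    t <- times[j]
    lvl <- interior0
    t_cur <- 0
    evs <- events[events[, "time"] <= t, , drop = FALSE]
    checkpoints <- rbind(evs, c(t, 1))
    for (k in seq_len(nrow(checkpoints))) {
      t_next <- checkpoints[k, 1]
      # relaxation over [t_cur, t_next], active only after onset
      lo <- max(t_cur, scenario$onset)
      if (scenario$rate > 0 && t_next > lo)
        lvl <- exterior - (exterior - lvl) * exp(-scenario$rate * (t_next - lo))
      lvl <- lvl * checkpoints[k, 2]
      t_cur <- t_next
    }
    out[j] <- lvl
  }
  out
}

#' Simulate a cargo-influx time-lapse
#'
#' Renders one soluble-dye frame per time point with the interior level
#' following the permeability scenario, and returns alongside it the analytic
#' ground-truth flux series (interior/exterior levels and the relative import
#' level `(I_out - I_in) / I_out`) that the image-based [flux_statistic()] is
#' benchmarked against.
#'
#' @param shape a [make_contour()] (the vesicle outline; it also receives the
#'   membrane ridge of `optics` in each frame).
#' @param optics an [optics_model()]; its `interior_level` is the initial
#'   interior dye level and `exterior_level` the (constant) exterior level.
#' @param scenario a [permeability_scenario()].
#' @param times frame acquisition times in minutes, strictly increasing,
#'   non-negative.
#' @param noise a [noise_model()] or `NULL`; frame `i` uses seed
#'   `noise$seed + i - 1` so frames are independent yet reproducible.
#' @param size frame side in pixels.
#' @return a list with `frames` (list of [image_frame()]) and `truth`
#'   (a [flux_series()] of the analytic levels).
#' @export
simulate_influx_stack <- function(shape, optics, scenario, times,
                                  noise = NULL, size = 512L) {
  stopifnot(inherits(scenario, "permeability_scenario"))
  if (any(times < 0)) stop_bad_arg("`times` must be non-negative")
  if (any(diff(times) <= 0)) stop_bad_arg("`times` must be strictly increasing")
  if (optics$exterior_level <= 0)
    stop_bad_arg("influx simulation needs a positive exterior level")
  lvl <- interior_level_at(scenario, times, optics$interior_level,
                           optics$exterior_level)
  frames <- vector("list", length(times))
  for (i in seq_along(times)) {
    opt_i <- optics
    opt_i$interior_level <- lvl[i]
    noise_i <- if (is.null(noise)) NULL else
      noise_model(noise$poisson_gain, noise$gaussian_sd, noise$seed + i - 1L)
    frames[[i]] <- render_guv_slice(shape, opt_i, noise_i, size = size,
                                    channel = "cargo", time = times[i])
  }
  truth <- flux_series(times, I_in = lvl,
                       I_out = rep(optics$exterior_level, length(times)))
  list(frames = frames, truth = truth)
}

#' Generate a synthetic FCS autocorrelation curve
#'
#' Evaluates the one-component 2D diffusion autocorrelation model
#' \deqn{G(\tau) = \frac{1}{N} \frac{1}{1 + \tau/\tau_D}}
#' at the requested lags and optionally adds zero-mean Gaussian noise. `N` is
#' the mean particle number in the detection area and `tau_D` the diffusion
#' time.
#'
#' @param N particle number, > 0.
#' @param tau_D diffusion time in seconds, > 0.
#' @param lags lag times in seconds, positive and increasing (default 64
#'   log-spaced lags from 1 us to 1 s).
#' @param noise_sd Gaussian noise s.d. added to G (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @return an [fcs_curve()].
#' @examples
#' generate_fcs_curve(10, 1e-3, lags = 1e-3)$G  # half amplitude: 0.05
#' @export
generate_fcs_curve <- function(N, tau_D,
                               lags = 10^seq(-6, 0, length.out = 64),
                               noise_sd = 0, seed = 1L) {
  check_scalar_pos(N, "N"); check_scalar_pos(tau_D, "tau_D")
  check_scalar_pos(noise_sd, "noise_sd", strict = FALSE)
  G <- (1 / N) / (1 + lags / tau_D)
  if (noise_sd > 0)
    G <- G + with_rng_seed(seed, rnorm(length(G), 0, noise_sd))
  fcs_curve(lags, G)
}

#' Generate a synthetic raft-binding time series
#'
#' Integrated membrane intensity following classical target-binding kinetics
#' \deqn{I(t) = I_{max} (1 - e^{-a t})} plus optional Gaussian noise.
#'
#' @param I_max plateau intensity, > 0.
#' @param a binding rate constant, 1/min, > 0.
#' @param times sampling times in minutes, non-negative increasing.
#' @param noise_sd Gaussian noise s.d. (intensity units).
#' @param seed RNG seed for the noise.
#' @return a [binding_series()].
#' @export
generate_binding_series <- function(I_max, a, times, noise_sd = 0, seed = 1L) {
  check_scalar_pos(I_max, "I_max"); check_scalar_pos(a, "a")
  if (any(times < 0) || any(diff(times) <= 0))
    stop_bad_arg("`times` must be non-negative and strictly increasing")
  I <- I_max * (1 - exp(-a * times))
  if (noise_sd > 0)
    I <- I + with_rng_seed(seed, rnorm(length(I), 0, noise_sd))
  binding_series(times, I)
}

#' Generate synthetic donor/acceptor emission spectra for raft states
#'
#' Forward-models ensemble FRET spectra for raft conformational states from
#' their donor-acceptor dye distances: the transfer efficiency
#' `E = 1 / (1 + (r/R0)^6)` splits a fixed total emission between a Gaussian
#' donor band and a Gaussian acceptor band.
#'
#' @param distances named numeric vector of dye-dye distances (nm) per state,
#'   e.g. `c("s-DR" = 7.2, "e-DR" = 3.1, "R-s-DR" = 7.2)`.
#' @param R0 Foerster radius in nm (configuration parameter; default 5.4).
#' @param wavelengths emission wavelengths (nm) to sample.
#' @param donor_peak,acceptor_peak band centres (nm).
#' @param band_sd Gaussian band width (nm).
#' @param total total integrated emission per state.
#' @param noise_sd Gaussian intensity noise; `seed` its RNG seed.
#' @param seed RNG seed.
#' @return a data frame with columns `wavelength`, `intensity`, `state`.
#' @export
generate_fret_spectra <- function(distances, R0 = 5.4,
                                  wavelengths = seq(540, 720, by = 2),
                                  donor_peak = 570, acceptor_peak = 670,
                                  band_sd = 18, total = 1000,
                                  noise_sd = 0, seed = 1L) {
  check_scalar_pos(R0, "R0")
  if (is.null(names(distances)) || any(!nzchar(names(distances))))
    stop_bad_arg("`distances` must be a named vector (one name per state)")
  out <- do.call(rbind, lapply(names(distances), function(st) {
    E <- 1 / (1 + (distances[[st]] / R0)^6)
    I <- total * ((1 - E) * stats::dnorm(wavelengths, donor_peak, band_sd) +
                  E * stats::dnorm(wavelengths, acceptor_peak, band_sd))
    data.frame(wavelength = wavelengths, intensity = I, state = st)
  }))
  if (noise_sd > 0)
    out$intensity <- pmax(0, out$intensity +
      with_rng_seed(seed, rnorm(nrow(out), 0, noise_sd)))
  out
}
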