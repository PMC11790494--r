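#' Simulate a coupled shape-recovery / cargo-influx time-lapse
#'
#' Generates the two-channel synthetic experiment in which a deformed vesicle
#' gradually recovers its spherical shape while cargo influx starts only
#' around the recovery point: the membrane-channel frames are rendered from a
#' mode-2 contour whose amplitude decays linearly to zero at `recovery_end`,
#' and the cargo-channel frames follow the permeability scenario.
#'
#' @param times frame times, minutes.
#' @param R vesicle base radius, micrometres.
#' @param amp0 initial mode-2 amplitude (fraction of `R`).
#' @param recovery_end time at which the amplitude reaches 0, minutes.
#' @param scenario a [permeability_scenario()] for the cargo channel.
#' @param optics_membrane,optics_cargo [optics_model()]s for the two channels.
#' @param noise a [noise_model()] or `NULL`.
#' @param size frame side, pixels.
#' @param center contour centre in micrometres; default centres the vesicle.
#' @return list with `membrane` (list of frames), `cargo` (list of frames),
#'   `truth` (data frame `time`, `amplitude`, `I_in`, `import`).
#' @export
simulate_remodeling_stack <- function(times, R = 10, amp0 = 0.12,
                                      recovery_end = 100,
                                      scenario = permeability_scenario(rate = 0.05, onset = 100),
                                      optics_membrane = optics_model(),
                                      optics_cargo = optics_model(
                                        membrane_peak = 100,
                                        exterior_level = 100, background = 0),
                                      noise = NULL, size = 512L,
                                      center = NULL) {
  if (any(times < 0) || any(diff(times) <= 0))
    stop_bad_arg("`times` must be non-negative and strictly increasing")
  if (is.null(center))
    center <- rep((size - 1) / 2 * optics_membrane$pixel_size, 2)
  amp <- amp0 * pmax(0, 1 - times / recovery_end)
  membrane <- cargo <- vector("list", length(times))
  lvl <- interior_level_at(scenario, times, optics_cargo$interior_level,
                           optics_cargo$exterior_level)
  for (i in seq_along(times)) {
    shp <- if (amp[i] > 0)
      make_contour(R, list(c(2, amp[i], 0)), center = center)
    else make_contour(R, center = center)
    noise_m <- if (is.null(noise)) NULL else
      noise_model(noise$poisson_gain, noise$gaussian_sd, noise$seed + 2L * i)
    noise_c <- if (is.null(noise)) NULL else
      noise_model(noise$poisson_gain, noise$gaussian_sd, noise$seed + 2L * i + 1L)
    membrane[[i]] <- render_guv_slice(shp, optics_membrane, noise_m, size,
                                      channel = "membrane", time = times[i])
    opt_c <- optics_cargo
    opt_c$interior_level <- lvl[i]
    cargo[[i]] <- render_guv_slice(shp, opt_c, noise_c, size,
                                   channel = "cargo", time = times[i])
  }
  list(membrane = membrane, cargo = cargo,
       truth = data.frame(time = times, amplitude = amp, I_in = lvl,
                          import = (optics_cargo$exterior_level - lvl) /
                            optics_cargo$exterior_level))
}

# Reject option lists with unknown keys; returns the merged options.
validate_options <- function(options, defaults) {
  unknown <- setdiff(names(options), names(defaults))
  if (length(unknown))
    stop_bad_arg("unknown option key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, options)
}

#' End-to-end coupled shape/influx analysis
#'
#' Runs the full analysis over an aligned two-channel time-lapse: per frame,
#' the membrane channel is traced and summarised by `SD_k`, and the cargo
#' channel is reduced to the relative import level. The result aligns both
#' statistics on one time axis and reports the shape-recovery time (first
#' frame from which `SD_k` stays at or below the deformation threshold), the
#' influx-onset time (first frame whose import level drops below
#' `influx_cutoff`), and the delay between them: a positive delay means influx
#' began only after full spherical recovery.
#'
#' @param membrane_frames,cargo_frames lists of [image_frame()], one per time
#'   point, equal length.
#' @param x_seed starting membrane seed for the tracer (pixels); required.
#' @param options named list overriding analysis options. Unknown keys are
#'   rejected (naming the key). Known keys: `center` (vesicle centre, px),
#'   `settings` (a [trace_settings()]), `threshold` (SD_k deformation
#'   threshold, default 0.026), `influx_cutoff` (import level below which
#'   influx has begun, default 0.95), `roi_in`, `roi_out` (flux ROI sides).
#' @return list of class `guv_pipeline`: `series` (data frame `time`, `sdk`,
#'   `deformed`, `import`), `recovery_time`, `influx_onset`, `onset_delay`.
#' @export
run_pipeline <- function(membrane_frames, cargo_frames, x_seed,
                         options = list()) {
  if (length(membrane_frames) != length(cargo_frames) || !length(membrane_frames))
    stop_bad_arg("need equal, non-zero numbers of membrane and cargo frames")
  opt <- validate_options(options, list(
    center = NULL, settings = trace_settings(), threshold = 0.026,
    influx_cutoff = 0.95, roi_in = 30, roi_out = 50))
  # the membrane channel, not the cargo channel, defines the vesicle centre
  if (is.null(opt$center)) opt$center <- estimate_center(membrane_frames[[1]])
  times <- vapply(membrane_frames, `[[`, numeric(1), "time")
  if (anyNA(times)) times <- seq_along(membrane_frames) - 1

  sdk <- numeric(length(membrane_frames))
  for (i in seq_along(membrane_frames)) {
    tr <- tryCatch(
      trace_contour(membrane_frames[[i]], x_seed = x_seed,
                    x0 = opt$center, settings = opt$settings),
      error = function(e) stop_bad_arg("shape tracing failed at frame ", i,
                                       " (t = ", times[i], " min): ",
                                       conditionMessage(e)))
    sdk[i] <- curvature_profile(tr, threshold = opt$threshold)$sdk
  }
  flux <- tryCatch(
    flux_statistic(cargo_frames, center = opt$center,
                   roi_in = opt$roi_in, roi_out = opt$roi_out),
    error = function(e) stop_bad_arg("flux analysis failed: ",
                                     conditionMessage(e)))
  series <- data.frame(time = times, sdk = sdk,
                       deformed = sdk > opt$threshold, import = flux$import)

  recovered <- rev(cumprod(rev(sdk <= opt$threshold))) == 1  # sustained recovery
  recovery_time <- if (any(recovered)) times[which(recovered)[1]] else NA_real_
  influx_onset <- if (any(series$import < opt$influx_cutoff))
    times[which(series$import < opt$influx_cutoff)[1]] else NA_real_
  structure(list(series = series, recovery_time = recovery_time,
                 influx_onset = influx_onset,
                 onset_delay = influx_onset - recovery_time,
                 options = opt),
            class = "guv_pipeline")
}

#' @export
print.guv_pipeline <- function(x, ...) {
  cat(sprintf("pipeline: %d frames; recovery at %s min, influx onset at %s min (delay %s min)\n",
              nrow(x$series), format(x$recovery_time), format(x$influx_onset),
              format(x$onset_delay)))
  invisible(x)
}
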