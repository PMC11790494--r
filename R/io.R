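#' Write / read frame stacks as multi-frame TIFF
#'
#' Frames are stored as 16-bit TIFF (one directory per time point) with a JSON
#' sidecar (`<path>.json`) recording the pixel size, channel, frame times and
#' the intensity scale factor, so a round trip reproduces intensities to
#' 16-bit quantisation.
#'
#' @param frames list of [image_frame()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_frames_tiff <- function(frames, path) {
  stopifnot(all(vapply(frames, inherits, logical(1), what = "guv_frame")))
  scale <- max(1e-12, max(vapply(frames, function(f) max(f$pixels), numeric(1))))
  tiff::writeTIFF(lapply(frames, function(f) f$pixels / scale), path,
                  bits.per.sample = 16L, compression = "none")
  meta <- list(pixel_size = frames[[1]]$pixel_size,
               channel = frames[[1]]$channel,
               times = vapply(frames, `[[`, numeric(1), "time"),
               scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param path TIFF path written by [write_frames_tiff()].
#' @rdname write_frames_tiff
#' @return for `read_frames_tiff`, a list of [image_frame()].
#' @export
read_frames_tiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(pixel_size = 1, channel = "unnamed", times = rep(NA_real_, length(imgs)),
            scale = 1)
  lapply(seq_along(imgs), function(i)
    image_frame(imgs[[i]] * meta$scale, meta$pixel_size, meta$channel,
                time = meta$times[i]))
}

#' Read and write two-column curve files
#'
#' FCS curves are stored as CSV with columns `lag_s`, `G` (plus optional
#' `weight`); binding series as CSV with columns `t_min`, `I`.
#'
#' @param curve an [fcs_curve()].
#' @param path CSV path.
#' @return the written path (writers) or the parsed object (readers).
#' @export
write_fcs_csv <- function(curve, path) {
  stopifnot(inherits(curve, "fcs_curve"))
  out <- data.frame(lag_s = curve$tau, G = curve$G)
  if ("weight" %in% names(curve)) out$weight <- curve$weight
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fcs_csv
#' @export
read_fcs_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("lag_s", "G") %in% names(d)))
    stop_bad_arg("FCS CSV needs columns lag_s, G")
  fcs_curve(d$lag_s, d$G, weights = d$weight)
}

#' @param series a [binding_series()].
#' @rdname write_fcs_csv
#' @export
write_binding_csv <- function(series, path) {
  stopifnot(inherits(series, "binding_series"))
  write.csv(data.frame(t_min = series$time, I = series$I), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_fcs_csv
#' @export
read_binding_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("t_min", "I") %in% names(d)))
    stop_bad_arg("binding CSV needs columns t_min, I")
  binding_series(d$t_min, d$I)
}

#' Write a per-GUV trace table
#'
#' One row per trace point: index, step angle, coordinates (sub-pixel vertex),
#' distance to the fitted centre and normalized local curvature.
#'
#' @param trace a [trace_contour()] result.
#' @param profile the matching [curvature_profile()].
#' @param path CSV path.
#' @export
write_trace_csv <- function(trace, profile, path) {
  stopifnot(inherits(trace, "guv_trace"), inherits(profile, "guv_curvature"))
  p <- trace_points(trace, "vertex")
  write.csv(data.frame(index = seq_len(nrow(p)) - 1L,
                       theta_deg = (seq_len(nrow(p)) - 1L) * trace$step_deg,
                       x = p[, 1], y = p[, 2],
                       R_i = profile$R_i, k_i = profile$k),
            path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis summary as JSON
#'
#' @param x a named list of scalar/vector results.
#' @param path JSON path.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
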