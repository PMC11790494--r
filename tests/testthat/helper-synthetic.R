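# Shared fixtures, built once per test run.

# Canonical noiseless circular GUV: R = 10 um at 0.1 um/px in a 512 px frame,
# centre at pixel (255, 255).
std_center_px <- c(255, 255)
std_shape <- make_contour(10, center = c(25.5, 25.5))
std_image <- render_guv_slice(std_shape, optics_model(), noise = NULL)

# Single-mode deformed shape used across tracing tests.
mode2_shape <- function(amp) make_contour(10, list(c(2, amp, 0)), center = c(25.5, 25.5))

trace_of <- function(shape, ..., optics = optics_model(), size = 512L) {
  img <- render_guv_slice(shape, optics, noise = NULL, size = size)
  r0 <- contour_radius(shape, 0) / optics$pixel_size
  ctr <- shape$center / optics$pixel_size
  trace_contour(img, x_seed = c(ctr[1] + r0, ctr[2]), ...)
}

# Independent separating-axis overlap test, written against the geometry
# directly (corner projections), used as the brute-force oracle for the
# compiled overlap code.
rects_overlap_r <- function(p1, p2, hl1, hw1, hl2, hw2, box) {
  d <- p2[1:2] - p1[1:2]
  d <- d - box * round(d / box)
  corners <- function(th, hl, hw) {
    u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
    rbind(hl * u + hw * v, hl * u - hw * v, -hl * u + hw * v, -hl * u - hw * v)
  }
  c1 <- corners(p1[3], hl1, hw1)
  c2 <- sweep(corners(p2[3], hl2, hw2), 2, d, "+")
  axes <- rbind(c(cos(p1[3]), sin(p1[3])), c(-sin(p1[3]), cos(p1[3])),
                c(cos(p2[3]), sin(p2[3])), c(-sin(p2[3]), cos(p2[3])))
  for (k in 1:4) {
    a <- axes[k, ]
    pr1 <- c1 %*% a; pr2 <- c2 %*% a
    if (max(pr1) <= min(pr2) || max(pr2) <= min(pr1)) return(FALSE)
  }
  TRUE
}

config_valid_r <- function(config) {
  p <- config$particles
  n <- nrow(p)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (rects_overlap_r(unlist(p[i, c("x", "y", "theta")]),
                        unlist(p[j, c("x", "y", "theta")]),
                        p$hl[i], p$hw[i], p$hl[j], p$hw[j], config$box))
      return(FALSE)
  }
  TRUE
}
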