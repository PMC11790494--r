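test_that("compiled overlap test agrees with the brute-force oracle on a state grid", {
  # two 70.8 x 55 rectangles, one fixed, the other swept over a grid of
  # displacements and orientations (including periodic wrap-around cases)
  hl <- 35.4; hw <- 27.5; box <- 500
  p1 <- c(250, 250, 0.3)
  xs <- seq(150, 350, length.out = 12)
  ys <- seq(150, 350, length.out = 12)
  ths <- seq(0, pi, length.out = 12)
  mism <- 0L; checked <- 0L; n_overlap <- 0L
  for (x in xs) for (y in ys) for (th in ths) {
    p2 <- c(x, y, th)
    a <- rect_pair_overlap_cpp(p1, p2, hl, hw, hl, hw, box)
    b <- rects_overlap_r(p1, p2, hl, hw, hl, hw, box)
    checked <- checked + 1L
    n_overlap <- n_overlap + a
    if (a != b) mism <- mism + 1L
  }
  expect_identical(mism, 0L)
  expect_identical(checked, 1728L)
  expect_gt(n_overlap, 0)        # the grid exercises both outcomes
  expect_lt(n_overlap, checked)
  # wrap-around: centres 490 and 10 are 20 nm apart across the boundary
  expect_true(rect_pair_overlap_cpp(c(490, 250, 0), c(10, 250, 0),
                                    hl, hw, hl, hw, box))
})

test_that("random sequential insertion yields valid configurations at the target coverage", {
  cfg <- init_raft_config(40, dims = c(70.8, 55), phi = 0.231, seed = 3)
  expect_true(config_valid(cfg))
  expect_true(config_valid_r(cfg))           # independent oracle
  expect_equal(cfg$phi, 0.231, tolerance = 1e-9)
  one <- init_raft_config(1, dims = c(70.8, 55), box = 400, seed = 1)
  expect_equal(one$phi, 70.8 * 55 / 400^2)
  expect_error(init_raft_config(100, dims = c(70.8, 55), phi = 0.9),
               "random sequential insertion")
})

test_that("Metropolis dynamics preserves the hard-core constraint and determinism", {
  cfg <- init_raft_config(30, dims = c(120, 25), phi = 0.18, seed = 5)
  tr <- run_mc(cfg, move_settings(sweeps = 300, seed = 9), record_every = 100)
  for (f in tr$frames) expect_true(config_valid_r(f))
  expect_gt(tr$acceptance, 0)
  # zero sweeps: output identical to input
  tr0 <- run_mc(cfg, move_settings(sweeps = 0, seed = 9))
  expect_identical(tr0$final$particles, cfg$particles)
  # fixed seed => identical trajectory
  tr2 <- run_mc(cfg, move_settings(sweeps = 300, seed = 9), record_every = 100)
  expect_identical(tr$final$particles, tr2$final$particles)
  tr3 <- run_mc(cfg, move_settings(sweeps = 300, seed = 10), record_every = 100)
  expect_false(identical(tr3$final$particles, tr2$final$particles))
})

test_that("gradual shape transformation conserves count, box and approximate coverage", {
  cfg <- init_raft_config(40, dims = c(70.8, 55), phi = 0.2, seed = 7)
  tf <- transform_shapes(cfg, c(190, 20), n_substeps = 30, relax_sweeps = 30,
                         moves = move_settings(translation_step = 5,
                                               rotation_step = 0.1, seed = 8))
  expect_true(config_valid_r(tf))
  expect_identical(nrow(tf$particles), 40L)
  expect_equal(unique(tf$particles$hl), 95)
  expect_equal(unique(tf$particles$hw), 10)
  # 70.8x55 -> 190x20 is area-preserving to ~2.4%, so phi moves by < 3%
  expect_lt(abs(tf$phi / cfg$phi - 3800 / 3894), 0.001)
  # identity transform: dimensions unchanged
  id <- transform_shapes(cfg, c(70.8, 55), n_substeps = 5, relax_sweeps = 5)
  expect_equal(unique(id$particles$hl), 35.4)
  # a single-step transform of crowded particles cannot complete: the
  # geometric obstruction is why gradual reconfiguration matters
  crowded <- init_raft_config(40, dims = c(70.8, 55), phi = 0.23, seed = 17)
  expect_error(transform_shapes(crowded, c(190, 20), n_substeps = 1,
                                relax_sweeps = 0, max_retries = 2),
               "stuck")
})

test_that("order metrics satisfy their symmetry and normalization identities", {
  mk <- function(theta, nx = 4, spacing = 30) {
    g <- expand.grid(x = spacing * (1:nx), y = spacing * (1:nx))
    new_raft_config(box = spacing * (nx + 1),
                    particles = data.frame(x = g$x, y = g$y, theta = theta,
                                           hl = 10, hw = 5))
  }
  # perfect alignment: S2 = S4 = 1, everything ordered, one cluster
  m1 <- order_metrics(mk(rep(0.4, 16)), neighbor_radius = 35)
  expect_equal(m1$S2, 1); expect_equal(m1$S4, 1)
  expect_equal(m1$ordered_fraction, 1)
  expect_equal(m1$mean_cluster_size, 16)
  # checkerboard 0/90 degrees: tetratic S4 = 1 while S2 < 0 on nearest pairs
  g <- expand.grid(i = 1:4, j = 1:4)
  th <- ifelse((g$i + g$j) %% 2 == 0, 0, pi / 2)
  m2 <- order_metrics(mk(th), neighbor_radius = 35)
  expect_equal(m2$S4, 1)
  expect_lt(m2$S2, 0)
  # global rotation by pi/2 leaves S4 unchanged
  cfg <- init_raft_config(30, dims = c(120, 25), phi = 0.15, seed = 2)
  m <- order_metrics(cfg)
  rot <- cfg; rot$particles$theta <- rot$particles$theta + pi / 2
  expect_equal(order_metrics(rot)$S4, m$S4, tolerance = 1e-12)
  expect_true(abs(m$S4) <= 1 && abs(m$S2) <= 1)
  expect_error(order_metrics(init_raft_config(1, box = 400)), "2 particles")
  expect_warning(order_metrics(cfg, neighbor_radius = 10), "width")
})
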