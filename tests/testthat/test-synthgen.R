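test_that("generators are deterministic given a seed and vary across seeds", {
  opt <- optics_params()
  a <- generate_dof_target_trial(opt, 40, n_frames = 3, seed = 7,
                                 width_px = 256, height_px = 16)
  b <- generate_dof_target_trial(opt, 40, n_frames = 3, seed = 7,
                                 width_px = 256, height_px = 16)
  c <- generate_dof_target_trial(opt, 40, n_frames = 3, seed = 8,
                                 width_px = 256, height_px = 16)
  expect_identical(a$frames, b$frames)
  expect_false(identical(a$frames, c$frames))
  # ground-truth model parameters do not depend on the seed
  expect_identical(a$meta$true_depth_um, c$meta$true_depth_um)

  s1 <- generate_interleaved_session(scene_spec(6, 4, 0.5), n_frames = 8,
                                     seed = 3, dims = c(64, 64))
  s2 <- generate_interleaved_session(scene_spec(6, 4, 0.5), n_frames = 8,
                                     seed = 3, dims = c(64, 64))
  expect_identical(s1$stack$frames, s2$stack$frames)
  expect_identical(s1$truth$neurons, s2$truth$neurons)
})

test_that("depth-of-field target focuses at the commanded depth", {
  opt <- optics_params(depth_per_pwm_um = 7.7, depth_offset_um = 0)
  tr <- generate_dof_target_trial(opt, 50, n_frames = 1, noise_sd = 0,
                                  seed = 1)
  expect_equal(tr$meta$true_depth_um, 385)
  # contrast envelope of the clean profile peaks at the focused column
  prof <- colMeans(tr$frames[, , 1])
  x <- tr$meta$x_um
  resid <- abs(prof - median(prof))
  # local contrast maximum: average |oscillation| in a one-period window
  win <- which(abs(x - 385) < 200)
  sm <- vapply(win, function(j) {
    mean(resid[abs(x - x[j]) <= tr$meta$period_um / 2])
  }, numeric(1))
  expect_lt(abs(x[win[which.max(sm)]] - 385), tr$meta$period_um / 2)
  expect_error(generate_dof_target_trial(opt, 120), "0, 100")
})

test_that("time-averaging a noisy trial improves SNR", {
  opt <- optics_params()
  tr <- generate_dof_target_trial(opt, 50, n_frames = 100, noise_sd = 5,
                                  seed = 2, width_px = 256, height_px = 16)
  clean <- generate_dof_target_trial(opt, 50, n_frames = 1, noise_sd = 0,
                                     seed = 2, width_px = 256,
                                     height_px = 16)$frames[, , 1]
  err_single <- sd(tr$frames[, , 1] - clean)
  err_avg <- sd(stack_mean(tr) - clean)
  expect_lt(err_avg, err_single / 5)  # ~1/sqrt(100) in expectation
})

test_that("identity optics produce flat-field, distortion-free grids", {
  opt <- optics_params(radial_distortion_k = 0, petzval_radius_um = 1e9,
                      petzval_center_um = c(0, 0, 1e9))
  g <- generate_grid_stack(opt, n_depths = 5, seed = 1, width_px = 96,
                           height_px = 96, noise_sd = 0)
  # flat field: every point is sharpest at the same depth
  expect_lt(diff(range(g$truth$z_opt_um)), 1e-6)
  # no distortion: image positions equal ideal positions
  expect_equal(g$truth$x_img_um, g$truth$x_ideal_um)
  expect_equal(g$truth$y_img_um, g$truth$y_ideal_um)
})

test_that("grid distortion displaces intersections radially, growing with radius", {
  opt <- optics_params(radial_distortion_k = 2e-6)
  g <- generate_grid_stack(opt, n_depths = 3, seed = 1, width_px = 160,
                           height_px = 160, noise_sd = 0)
  tr <- g$truth
  r_ideal <- sqrt(tr$x_ideal_um^2 + tr$y_ideal_um^2)
  r_img <- sqrt(tr$x_img_um^2 + tr$y_img_um^2)
  dr <- r_img - r_ideal
  expect_true(all(dr[r_ideal > 0] > 0))
  ord <- order(r_ideal)
  expect_true(all(diff(dr[ord]) >= -1e-9))
})

test_that("bead volumes honour separation, chroma shift and argmax truth", {
  opt0 <- optics_params(chroma_shift_um = c(0, 0, 0))
  bv0 <- generate_bead_volumes(opt0, n_beads = 4, seed = 5, noise_sd = 0)
  expect_identical(bv0$green, bv0$red)  # zero shift: channels identical

  pos <- as.matrix(bv0$true_positions_um)
  dmin <- min(dist(pos))
  expect_gte(dmin, 3 * 15)  # >= 3 bead diameters apart

  bv1 <- generate_bead_volumes(optics_params(), n_beads = 1, seed = 2,
                               noise_sd = 0)
  am <- which(bv1$green == max(bv1$green), arr.ind = TRUE)[1, ]
  vox <- bv1$voxel_um
  truth <- as.numeric(bv1$true_positions_um[1, ])
  expect_lt(abs((am[2] - 1) * vox[2] - truth[1]), vox[2])
  expect_lt(abs((am[1] - 1) * vox[1] - truth[2]), vox[1])
  expect_lt(abs((am[3] - 1) * vox[3] - truth[3]), vox[3])

  expect_error(generate_bead_volumes(optics_params(), n_beads = 2, seed = 1,
                                     vol_px = c(8, 8, 4)),
               "too small")
})

test_that("interleaved sessions alternate channels with exact bookkeeping", {
  sc <- scene_spec(8, 6, 1, transient_rate_hz = 0.3, noise_sd = 0,
                   jitter_sd_px = 0)
  sess <- generate_interleaved_session(sc, n_frames = 20, fps = 10, seed = 4,
                                       dims = c(80, 80))
  tr <- sess$truth
  # overlap_fraction = 1: every red neuron is co-labeled
  expect_equal(length(tr$colabel_ids), 6)
  expect_true(all(tr$neurons$channel[tr$red_ids] == "both"))
  # red (even-index, odd 1-based) frames are static
  red_frames <- sess$stack$frames[, , seq(2, 20, 2)]
  expect_lt(max(abs(sweep(red_frames, c(1, 2), red_frames[, , 1]))), 1e-9)
  # green frames vary in time (calcium transients present)
  grn_frames <- sess$stack$frames[, , seq(1, 20, 2)]
  expect_gt(max(abs(sweep(grn_frames, c(1, 2), grn_frames[, , 1]))), 1)
  # every green neuron has at least one transient
  expect_true(all(lengths(tr$events_s) >= 1))

  # no dynamics at all: both de-interleaved streams constant
  sc0 <- scene_spec(5, 3, 0.4, transient_rate_hz = 0, noise_sd = 0,
                    jitter_sd_px = 0)
  s0 <- generate_interleaved_session(sc0, n_frames = 8, seed = 1,
                                     dims = c(64, 64))
  for (idx in list(seq(1, 8, 2), seq(2, 8, 2))) {
    fr <- s0$stack$frames[, , idx]
    expect_lt(max(abs(sweep(fr, c(1, 2), fr[, , 1]))), 1e-9)
  }
})
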