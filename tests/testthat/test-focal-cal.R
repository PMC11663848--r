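opt <- optics_params()

test_that("column_average_profile equals the per-column mean", {
  st <- frame_stack(array(7, dim = c(5, 6, 3)))
  prof <- column_average_profile(st, opt)
  expect_equal(prof$intensity, rep(7, 6))
  expect_equal(nrow(prof), 6)

  set.seed(1)
  fr <- matrix(runif(48), 6, 8)
  prof1 <- column_average_profile(frame_stack(fr), opt)
  expect_equal(prof1$intensity, colMeans(fr))

  # independent double-loop oracle on a generated trial
  tr <- generate_dof_target_trial(opt, 30, n_frames = 4, seed = 2,
                                  width_px = 128, height_px = 8)
  prof2 <- column_average_profile(tr, opt)
  oracle <- numeric(128)
  for (j in 1:128) {
    acc <- 0
    for (t in 1:4) acc <- acc + mean(tr$frames[, j, t])
    oracle[j] <- acc / 4
  }
  expect_equal(prof2$intensity, oracle)
  expect_equal(prof2$x_um[2] - prof2$x_um[1],
               opt$pixel_size_um / opt$magnification)
})

test_that("PWM counts convert to percent over the 10-bit range", {
  expect_equal(pwm_counts_to_percent(0), 0)
  expect_equal(pwm_counts_to_percent(1023), 100)
  expect_equal(pwm_counts_to_percent(512), 512 / 1023 * 100)
  expect_error(pwm_counts_to_percent(1024))
  expect_error(pwm_counts_to_percent(-1))
})

test_that("envelope fit recovers a pure Gaussian envelope centre", {
  x <- seq(0, 400, by = 1)
  y <- exp(-((x - 200) / 40)^2)
  fit <- fit_envelope_sinusoid(tibble::tibble(x_um = x, intensity = y),
                               detrend = FALSE)
  expect_lt(abs(fit$b - 200), 0.5)
  expect_error(
    fit_envelope_sinusoid(tibble::tibble(x_um = x, intensity = rep(1, 401))),
    "zero variance")
})

test_that("envelope fit centre is translation-equivariant", {
  tr <- generate_dof_target_trial(opt, 50, n_frames = 5, noise_sd = 0.5,
                                  seed = 9)
  prof <- column_average_profile(tr, opt)
  fit0 <- fit_envelope_sinusoid(prof)
  for (dx in c(35, -70)) {
    shifted <- tibble::tibble(x_um = prof$x_um + dx,
                              intensity = prof$intensity)
    fit1 <- fit_envelope_sinusoid(shifted)
    expect_lt(abs(fit1$b - (fit0$b + dx)), 0.05)
  }
})

test_that("full model never fits worse than the nested pure-envelope model", {
  for (seed in 1:3) {
    tr <- generate_dof_target_trial(opt, 20 + 25 * seed, n_frames = 3,
                                    noise_sd = 1, seed = seed,
                                    width_px = 512, height_px = 16)
    prof <- column_average_profile(tr, opt)
    fit <- fit_envelope_sinusoid(prof)
    # pure envelope (no harmonic): least-squares over the same (b, c) grid
    x <- prof$x_um
    y <- prof$intensity - median(prof$intensity)
    sse_env <- function(par) {
      e <- exp(-((x - par[1]) / exp(par[2]))^2)
      cf <- sum(e * y) / sum(e * e)
      sum((y - cf * e)^2)
    }
    best_env <- min(vapply(seq(50, 950, by = 50), function(b0) {
      optim(c(b0, log(60)), sse_env)$value
    }, numeric(1)))
    expect_lte(fit$sse, best_env + 1e-6)
  }
})

test_that("grid-search oracle and optimizer agree on the envelope centre", {
  tr <- generate_dof_target_trial(opt, 65, n_frames = 10, noise_sd = 0.5,
                                  seed = 21)
  prof <- column_average_profile(tr, opt)
  fit <- fit_envelope_sinusoid(prof)
  oracle <- grid_search_envelope(prof)
  expect_lt(abs(fit$b - oracle$b), 0.5)
  expect_lt(abs(fit$b - tr$meta$true_depth_um), 2)
})

test_that("focal depth maps envelope displacement one-to-one at 45 degrees", {
  tr <- generate_dof_target_trial(opt, 50, n_frames = 3, noise_sd = 0,
                                  seed = 1, width_px = 512, height_px = 8)
  fit <- fit_envelope_sinusoid(column_average_profile(tr, opt))
  expect_equal(trial_focal_depth(fit, opt, x_ref = fit$b, depth_ref = 120),
               120)
  d0 <- trial_focal_depth(fit, opt)
  expect_equal(trial_focal_depth(fit, opt, x_ref = -10), d0 + 10)
  expect_equal(d0, fit$b)
})

test_that("depth model is exact on collinear points and guards degeneracy", {
  pts <- tibble::tibble(pwm_percent = c(0, 25, 50, 75, 100),
                        depth_um = 2 * c(0, 25, 50, 75, 100) + 5)
  m <- fit_depth_model(pts)
  expect_equal(m$slope, 2)
  expect_equal(m$intercept, 5)
  expect_equal(m$r_squared, 1)
  expect_equal(glance(m)$slope, 2)
  expect_equal(tidy(m)$estimate, c(5, 2))

  const <- tibble::tibble(pwm_percent = c(0, 50, 100), depth_um = c(7, 7, 7))
  expect_warning(mc <- fit_depth_model(const), "Zero-variance")
  expect_equal(mc$slope, 0)
  expect_equal(mc$r_squared, 0)

  expect_error(fit_depth_model(tibble::tibble(pwm_percent = c(10, 10),
                                              depth_um = c(1, 2))),
               "identical")
})

test_that("a calibrated sweep recovers the generator's depth response", {
  pwms <- seq(0, 100, length.out = 8)
  trials <- lapply(seq_along(pwms), function(i) {
    generate_dof_target_trial(opt, pwms[i], n_frames = 5, noise_sd = 0.5,
                              seed = 100 + i)
  })
  sweep <- calibrate_focal_sweep(trials, opt)
  expect_lt(abs(sweep$model$slope - opt$depth_per_pwm_um) /
              opt$depth_per_pwm_um, 0.05)
  expect_gt(sweep$model$r_squared, 0.95)
  # depth origin: mid-field reference subtracted from every trial
  expect_equal(sweep$trials$depth_um, sweep$trials$b - sweep$x_ref_um)
})
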