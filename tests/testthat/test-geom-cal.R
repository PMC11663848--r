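opt0 <- optics_params()

test_that("grid intersections are localised to sub-pixel on clean grids", {
  g <- generate_grid_stack(opt0, n_depths = 8, seed = 3, noise_sd = 0,
                           width_px = 160, height_px = 160)
  det <- detect_grid_intersections(focus_projection(g$frames), 25, opt0)
  expect_gte(nrow(det$points), 16)
  err <- vapply(seq_len(nrow(det$points)), function(i) {
    min(sqrt((g$truth$x_px - det$points$x_det_px[i])^2 +
               (g$truth$y_px - det$points$y_det_px[i])^2))
  }, numeric(1))
  expect_lt(max(err), 0.25)

  expect_error(detect_grid_intersections(matrix(0, 64, 64), 25, opt0))
})

test_that("similarity alignment absorbs a rotated grid", {
  sp_px <- 25 / (opt0$pixel_size_um / opt0$magnification)
  straight <- render_grid_image(160, 160, sp_px)
  rotated <- render_grid_image(160, 160, sp_px, theta = 2 * pi / 180)
  d0 <- detect_grid_intersections(straight, 25, opt0)
  d2 <- detect_grid_intersections(rotated, 25, opt0)
  resid <- function(d) {
    q <- duoscope:::apply_similarity_inv(
      cbind(d$points$x_det_um, d$points$y_det_um), d$similarity)
    sqrt(mean((q[, 1] - d$points$x_ideal_um)^2 +
                (q[, 2] - d$points$y_ideal_um)^2))
  }
  expect_lt(abs(resid(d2) - resid(d0)), 0.15)
  # the fitted rotation matches the injected one
  expect_lt(abs(Arg(d2$similarity$a) * 180 / pi - 2), 0.2)
})

test_that("distortion coefficient is identified and scale is absorbed", {
  # detected = ideal: no distortion at all
  u <- as.matrix(expand.grid(x = (-3:3) * 25, y = (-3:3) * 25))
  mkdet <- function(p) structure(list(points = tibble::tibble(
    x_det_um = p[, 1], y_det_um = p[, 2],
    x_ideal_um = u[, 1], y_ideal_um = u[, 2]), spacing_um = 25),
    class = "grid_detection")
  d0 <- measure_distortion(mkdet(u))
  expect_equal(d0$k_hat, 0)
  expect_equal(max(abs(d0$profile$dr_um)), 0)

  # pure scale perturbation: absorbed by the similarity fit
  ds <- measure_distortion(mkdet(u * 1.04))
  expect_lt(abs(ds$k_hat), 1e-12)

  # injected radial distortion recovered from the generated image
  optk <- optics_params(radial_distortion_k = 1e-6)
  g <- generate_grid_stack(optk, n_depths = 8, seed = 2, width_px = 192,
                           height_px = 192)
  det <- detect_grid_intersections(focus_projection(g$frames), 25, optk)
  dk <- measure_distortion(det)
  expect_lt(abs(dk$k_hat - 1e-6) / 1e-6, 0.1)

  # collinear points are rejected
  lin <- cbind(seq(-75, 75, by = 25), 0)
  bad <- structure(list(points = tibble::tibble(
    x_det_um = lin[, 1], y_det_um = lin[, 2],
    x_ideal_um = lin[, 1], y_ideal_um = lin[, 2]), spacing_um = 25),
    class = "grid_detection")
  expect_error(measure_distortion(bad), "collinear")
})

test_that("flat-field scans put every point's optimum at the same depth", {
  optf <- optics_params(petzval_radius_um = 1e9,
                        petzval_center_um = c(0, 0, 1e9))
  g <- generate_grid_stack(optf, n_depths = 9, seed = 4, width_px = 128,
                           height_px = 128, noise_sd = 0.2)
  det <- detect_grid_intersections(focus_projection(g$frames), 25, optf)
  fp <- optimal_focus_per_point(g$depths_um, g$frames, det$points,
                                window_px = 18, optics = optf)
  best <- g$depths_um[4]  # apex depth sits 3 steps into the scan
  step <- g$depths_um[2] - g$depths_um[1]
  expect_true(all(abs(fp$z_opt_um[fp$reliable] - best) <= step / 2))
})

test_that("per-point focal optima track the Petzval surface", {
  g <- generate_grid_stack(opt0, n_depths = 16, seed = 5, width_px = 160,
                           height_px = 160)
  det <- detect_grid_intersections(focus_projection(g$frames), 25, opt0)
  fp <- optimal_focus_per_point(g$depths_um, g$frames, det$points,
                                window_px = 18, optics = opt0)
  truth_z <- vapply(seq_len(nrow(fp)), function(i) {
    j <- which.min((g$truth$x_px - fp$x_px[i])^2 +
                     (g$truth$y_px - fp$y_px[i])^2)
    g$truth$z_opt_um[j]
  }, numeric(1))
  ok <- fp$reliable
  expect_gt(mean(ok), 0.8)
  expect_true(all(abs(fp$z_opt_um[ok] - truth_z[ok]) <= 9.6))
})

test_that("sphere fit is exact on noise-free points and rejects coplanarity", {
  set.seed(42)
  ctr <- c(10, -5, 343.1); R <- 343.1
  th <- runif(8, 0, pi / 6); ph <- runif(8, 0, 2 * pi)
  pts <- tibble::tibble(
    x_um = ctr[1] + R * sin(th) * cos(ph),
    y_um = ctr[2] + R * sin(th) * sin(ph),
    z_um = ctr[3] - R * cos(th))
  sf <- fit_petzval_sphere(pts)
  expect_lt(abs(sf$radius - R) / R, 1e-9)
  expect_lt(max(abs(sf$center - ctr)), 1e-6)
  expect_lt(sf$rms_residual, 1e-9)

  cop <- tibble::tibble(x_um = c(0, 1, 0, 1), y_um = c(0, 0, 1, 1),
                        z_um = rep(2, 4))
  expect_error(fit_petzval_sphere(cop), "coplanar")
})

test_that("sphere fit tolerates noise and matches a nonlinear oracle", {
  set.seed(7)
  ctr <- c(0, 0, 343.1); R <- 343.1
  lat <- expand.grid(x = seq(-250, 250, 50), y = seq(-250, 250, 50))
  lat <- lat[lat$x^2 + lat$y^2 < 300^2, ]
  pts <- tibble::tibble(
    x_um = lat$x, y_um = lat$y,
    z_um = ctr[3] - sqrt(R^2 - lat$x^2 - lat$y^2) + rnorm(nrow(lat), sd = 2))
  sf <- fit_petzval_sphere(pts)
  expect_lt(abs(sf$radius - R) / R, 0.05)

  # independent oracle: direct nonlinear minimisation of radial residuals
  obj <- function(par) {
    sum((sqrt((pts$x_um - par[1])^2 + (pts$y_um - par[2])^2 +
                (pts$z_um - par[3])^2) - par[4])^2)
  }
  o <- optim(c(0, 0, 300, 300), obj, method = "BFGS",
             control = list(maxit = 1000, reltol = 1e-12))
  expect_lt(abs(sf$radius - o$par[4]) / o$par[4], 0.01)
})

test_that("sphere fit is equivariant under rigid translation", {
  set.seed(3)
  g <- expand.grid(x = seq(-80, 80, by = 40), y = seq(-80, 80, by = 40))
  z <- 343.1 - sqrt(343.1^2 - g$x^2 - g$y^2) + rnorm(nrow(g), sd = 1)
  pts <- tibble::tibble(x_um = g$x, y_um = g$y, z_um = z)
  s0 <- fit_petzval_sphere(pts)
  sh <- fit_petzval_sphere(dplyr::mutate(pts, x_um = x_um + 50,
                                         y_um = y_um - 30, z_um = z_um + 7))
  expect_equal(sh$radius, s0$radius, tolerance = 1e-9)
  expect_equal(sh$center, s0$center + c(50, -30, 7), tolerance = 1e-6)
})

test_that("the reference depth maximises the count of in-focus points", {
  g <- generate_grid_stack(opt0, n_depths = 12, seed = 6, width_px = 128,
                           height_px = 128)
  det <- detect_grid_intersections(focus_projection(g$frames), 25, opt0)
  fp <- optimal_focus_per_point(g$depths_um, g$frames, det$points,
                                window_px = 18, optics = opt0)
  z0 <- reference_focal_depth(fp, g$depths_um)
  # most points lie near the apex, whose depth is ~0 for default optics
  expect_lt(abs(z0 - 0), 2 * 9.6)
})
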