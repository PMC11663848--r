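# Synthetic-data generators with exact ground truth.
#
# Every generator is deterministic given (parameters, seed). Geometry is in
# object-space micrometres; images are matrices [y, x] with x = column.

#' Simulate a 45-degree depth-of-field target trial
#'
#' Renders a video of a 15 lp/mm vertical line target (66.67 um object-space
#' period) mounted at 45 degrees, so the target's depth increases linearly
#' across x at 1 um per object-space um. Columns whose depth is far from the
#' current focal plane are defocused: the grating is rendered with the
#' contrast a Gaussian blur of sigma `defocus_blur_gain * |depth(x) -
#' focus|` (clamped below at 0.3 px) leaves on a pure harmonic,
#' `exp(-2 pi^2 sigma^2 / T^2)`. The focused band is therefore a Gaussian
#' contrast envelope centred on the column whose depth equals the focal
#' depth set by the PWM duty cycle.
#'
#' @param optics An [optics_params()] object; `depth_per_pwm_um` and
#'   `depth_offset_um` define the ground-truth focal depth
#'   `depth_offset_um + depth_per_pwm_um * pwm_percent`.
#' @param pwm_percent Duty cycle in `[0, 100]`.
#' @param n_frames Frames per trial (>= 1); 100 matches a typical sweep.
#' @param noise_sd Additive Gaussian noise sd per pixel per frame.
#' @param seed Integer RNG seed.
#' @param width_px,height_px Frame size in pixels.
#' @param period_um Line-pair period in object um (66.67 = 15 lp/mm).
#' @return A [frame_stack] whose `meta` carries the ground truth:
#'   `true_depth_um` (= focused column position in object um) and
#'   `x_um` (per-column object-space positions).
#' @export
generate_dof_target_trial <- function(optics, pwm_percent, n_frames = 100,
                                      noise_sd = 0.5, seed = 1,
                                      width_px = 768, height_px = 64,
                                      period_um = 1000 / 15) {
  stopifnot(inherits(optics, "optics_params"), n_frames >= 1)
  if (!is.finite(pwm_percent) || pwm_percent < 0 || pwm_percent > 100) {
    abort("`pwm_percent` must lie in [0, 100].")
  }
  pitch <- object_pixel_um(optics)
  x_um <- (seq_len(width_px) - 1) * pitch
  focal <- optics$depth_offset_um + optics$depth_per_pwm_um * pwm_percent
  sigma <- pmax(optics$defocus_blur_gain * abs(x_um - focal), 0.3 * pitch)
  contrast <- exp(-2 * pi^2 * sigma^2 / period_um^2)
  offset <- 100
  amp <- 50
  profile <- offset + amp * contrast * cos(2 * pi * x_um / period_um)
  clean <- matrix(profile, nrow = height_px, ncol = width_px, byrow = TRUE)
  frames <- with_seed(seed, {
    out <- array(0, dim = c(height_px, width_px, n_frames))
    for (t in seq_len(n_frames)) {
      fr <- clean
      if (noise_sd > 0) fr <- fr + matrix(rnorm(length(clean), sd = noise_sd),
                                          nrow = height_px)
      out[, , t] <- fr
    }
    out
  })
  frame_stack(frames, fps = 10, channel = "green", pwm_percent = pwm_percent,
              meta = list(true_depth_um = focal, x_um = x_um,
                          period_um = period_um, noise_sd = noise_sd))
}

# best-focus depth of the Petzval surface at lateral position (x, y),
# coordinates relative to the optical axis; lower hemisphere (apex nearest)
petzval_z <- function(x, y, optics) {
  ctr <- optics$petzval_center_um
  R <- optics$petzval_radius_um
  rho2 <- (x - ctr[1])^2 + (y - ctr[2])^2
  if (any(rho2 >= R^2)) abort("Field extends beyond the Petzval sphere radius.")
  ctr[3] - sqrt(R^2 - rho2)
}

# forward radial distortion about the field centre: u (ideal, um) -> image um
distort_radial <- function(u, k) u * (1 + k * rowSums(u^2))

# inverse by two Newton steps (k * r^2 << 1 in all realistic settings)
undistort_radial <- function(p, k) {
  u <- p
  for (i in 1:3) {
    r2 <- rowSums(u^2)
    u <- p / (1 + k * r2)
  }
  u
}

#' Simulate a calibration-grid focal stack
#'
#' Renders a square fluorescent grid of stated spacing, warped by single-
#' coefficient radial distortion, imaged at a ladder of focal depths
#' through a field-curved (Petzval) optic: each grid point is sharpest at
#' the depth where the Petzval sphere crosses its lateral position.
#'
#' @param optics An [optics_params()] object (`radial_distortion_k`,
#'   `petzval_radius_um`, `petzval_center_um`, `defocus_blur_gain` used).
#' @param spacing_um Grid line spacing in object um.
#' @param depth_step_um Focal-depth increment between frames.
#' @param n_depths Number of depths scanned (>= 3).
#' @param seed Integer RNG seed.
#' @param width_px,height_px Frame size in pixels; the default field spans
#'   about +/-230 um in object space, a lateral extent whose field-
#'   curvature sag (88-230 um on a 343 um sphere) fills a 36-step, 9.6 um
#'   focal ladder.
#' @param noise_sd Additive Gaussian noise sd.
#' @param line_width_um Intrinsic (in-focus) Gaussian half-width of a line.
#' @return A list with `depths_um` (numeric), `frames` (list of matrices)
#'   and `truth`, a tibble of true intersections: ideal lattice position,
#'   distorted image position (both in um relative to the field centre),
#'   pixel position, and the per-point optimal depth `z_opt_um`.
#' @export
generate_grid_stack <- function(optics, spacing_um = 25, depth_step_um = 9.6,
                                n_depths = 36, seed = 1,
                                width_px = 336, height_px = 336,
                                noise_sd = 0.5, line_width_um = 1.5) {
  stopifnot(inherits(optics, "optics_params"), spacing_um > 0, n_depths >= 3)
  pitch <- object_pixel_um(optics)
  cx <- (width_px - 1) / 2
  cy <- (height_px - 1) / 2
  # pixel coordinates in um relative to field centre
  px_x <- ((seq_len(width_px) - 1) - cx) * pitch
  px_y <- ((seq_len(height_px) - 1) - cy) * pitch
  X <- matrix(px_x, nrow = height_px, ncol = width_px, byrow = TRUE)
  Y <- matrix(px_y, nrow = height_px, ncol = width_px)
  k <- optics$radial_distortion_k
  # ideal-space coordinates of each pixel (inverse distortion)
  U <- undistort_radial(cbind(as.vector(X), as.vector(Y)), k)
  Ux <- matrix(U[, 1], nrow = height_px)
  Uy <- matrix(U[, 2], nrow = height_px)
  zopt_px <- matrix(petzval_z(U[, 1], U[, 2], optics), nrow = height_px)
  # distance to nearest vertical / horizontal grid line, in ideal space
  dline <- function(u) abs((u + spacing_um / 2) %% spacing_um - spacing_um / 2)
  dv <- dline(Ux)
  dh <- dline(Uy)

  # scan depths centred a little below the Petzval apex
  apex_z <- petzval_z(optics$petzval_center_um[1], optics$petzval_center_um[2],
                      optics)
  depths <- apex_z - 3 * depth_step_um + (seq_len(n_depths) - 1) * depth_step_um

  frames <- with_seed(seed, lapply(depths, function(z) {
    sigma <- pmax(optics$defocus_blur_gain * abs(z - zopt_px), 0.3 * pitch)
    w2 <- line_width_um^2 + sigma^2
    ampl <- line_width_um / sqrt(w2)
    img <- 20 +
      80 * ampl * (exp(-dv^2 / (2 * w2)) + exp(-dh^2 / (2 * w2)))
    if (noise_sd > 0) img <- img + matrix(rnorm(length(img), sd = noise_sd),
                                          nrow = height_px)
    img
  }))

  # true intersections: ideal lattice points comfortably inside the field
  margin <- spacing_um * 0.6
  half_w <- (width_px - 1) / 2 * pitch
  half_h <- (height_px - 1) / 2 * pitch
  gx <- seq(-floor((half_w - margin) / spacing_um),
            floor((half_w - margin) / spacing_um)) * spacing_um
  gy <- seq(-floor((half_h - margin) / spacing_um),
            floor((half_h - margin) / spacing_um)) * spacing_um
  lattice <- expand.grid(x = gx, y = gy)
  warped <- distort_radial(cbind(lattice$x, lattice$y), k)
  truth <- tibble::tibble(
    x_ideal_um = lattice$x, y_ideal_um = lattice$y,
    x_img_um = warped[, 1], y_img_um = warped[, 2],
    x_px = warped[, 1] / pitch + cx, y_px = warped[, 2] / pitch + cy,
    z_opt_um = petzval_z(lattice$x, lattice$y, optics)
  )
  list(depths_um = depths, frames = frames, truth = truth,
       spacing_um = spacing_um, optics = optics, pitch_um = pitch)
}

#' Simulate two-channel fluorescent bead volumes
#'
#' Places beads (3-D Gaussian intensity profiles, laterally of the stated
#' diameter and axially elongated as a focal scan renders them) at random
#' well-separated positions; the red-channel volume shows the same beads
#' displaced by the chromatic offset `optics$chroma_shift_um`.
#'
#' @param optics An [optics_params()] object (`chroma_shift_um` used).
#' @param n_beads Number of beads (>= 1).
#' @param bead_diameter_um Bead diameter in um.
#' @param seed Integer RNG seed.
#' @param vol_px Integer length-3: volume size (ny, nx, nz) in voxels.
#' @param voxel_um Numeric length-3: voxel pitch (dy, dx, dz) in um;
#'   lateral pitch defaults to the optics' object pixel and the axial
#'   pitch to a 9.6 um focal-scan step.
#' @param noise_sd Additive Gaussian noise sd.
#' @param axial_sigma_um Axial intensity half-width of a bead in the scan.
#' @return A list with `green`, `red` (3-D arrays `[y, x, z]`),
#'   `true_positions_um` (tibble: green-channel bead centres, x/y relative
#'   to volume corner), `voxel_um` and the injected `chroma_shift_um`.
#' @export
generate_bead_volumes <- function(optics, n_beads = 8, bead_diameter_um = 15,
                                  seed = 1, vol_px = c(224, 224, 56),
                                  voxel_um = NULL, noise_sd = 0.2,
                                  axial_sigma_um = 18) {
  stopifnot(inherits(optics, "optics_params"), n_beads >= 1)
  pitch <- object_pixel_um(optics)
  if (is.null(voxel_um)) voxel_um <- c(pitch, pitch, 9.6)
  ny <- vol_px[1]; nx <- vol_px[2]; nz <- vol_px[3]
  ext <- c(ny, nx, nz) * voxel_um  # volume extent in um (y, x, z)
  shift <- optics$chroma_shift_um  # (dx, dy, dz), red minus green
  sep_min <- 3 * bead_diameter_um

  # margin so both channels' beads stay inside the volume
  marg_xy <- bead_diameter_um * 2 + max(abs(shift[1:2]))
  marg_z <- axial_sigma_um * 2 + abs(shift[3])
  lo <- c(marg_xy, marg_xy, marg_z)
  hi <- c(ext[2] - marg_xy, ext[1] - marg_xy, ext[3] - marg_z)  # (x, y, z)
  if (any(hi <= lo)) abort("Volume too small to place beads with margins.")

  pos <- with_seed(seed, {
    pts <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(pts) < n_beads) {
      cand <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]),
                runif(1, lo[3], hi[3]))
      # separation enforced laterally: a bead slide spreads in x-y, and
      # lateral spacing keeps cross-channel matching unambiguous
      ok <- nrow(pts) == 0 ||
        min(sqrt(rowSums(sweep(pts[, 1:2, drop = FALSE], 2,
                               cand[1:2])^2))) >= sep_min
      if (ok) pts <- rbind(pts, cand)
      tries <- tries + 1
      if (tries > 20000) abort("Volume too small to place beads this far apart.")
    }
    pts
  })
  colnames(pos) <- c("x_um", "y_um", "z_um")

  sig_lat <- bead_diameter_um / 4
  render <- function(centers) {
    vol <- array(0, dim = c(ny, nx, nz))
    xs <- (seq_len(nx) - 1) * voxel_um[2]
    ys <- (seq_len(ny) - 1) * voxel_um[1]
    zs <- (seq_len(nz) - 1) * voxel_um[3]
    for (i in seq_len(nrow(centers))) {
      gx <- exp(-(xs - centers[i, 1])^2 / (2 * sig_lat^2))
      gy <- exp(-(ys - centers[i, 2])^2 / (2 * sig_lat^2))
      gz <- exp(-(zs - centers[i, 3])^2 / (2 * axial_sigma_um^2))
      lat <- 100 * outer(gy, gx)
      for (kz in seq_len(nz)) if (gz[kz] > 1e-8) {
        vol[, , kz] <- vol[, , kz] + lat * gz[kz]
      }
    }
    vol
  }
  green <- render(pos)
  red <- render(sweep(pos, 2, c(shift[1], shift[2], shift[3]), `+`))
  if (noise_sd > 0) {
    nz_noise <- with_seed(seed + 1L, list(
      g = array(rnorm(length(green), sd = noise_sd), dim = dim(green)),
      r = array(rnorm(length(red), sd = noise_sd), dim = dim(red))
    ))
    green <- green + nz_noise$g
    red <- red + nz_noise$r
  }
  list(green = green, red = red,
       true_positions_um = tibble::as_tibble(as.data.frame(pos)),
       voxel_um = voxel_um, chroma_shift_um = shift)
}

# gaussian soma footprint centred at (x0, y0), truncated at small weight
soma_footprint <- function(x0, y0, sigma_px, ny, nx) {
  r <- ceiling(4 * sigma_px)
  xs <- max(1, round(x0) - r + 1):min(nx, round(x0) + r + 1)
  ys <- max(1, round(y0) - r + 1):min(ny, round(y0) + r + 1)
  w <- outer(exp(-((ys - 1) - y0)^2 / (2 * sigma_px^2)),
             exp(-((xs - 1) - x0)^2 / (2 * sigma_px^2)))
  w[w < 1e-4] <- 0
  m <- matrix(0, ny, nx)
  m[ys, xs] <- w
  m
}

#' Simulate an interleaved two-channel calcium-imaging session
#'
#' Generates an alternating-illumination frame stream: even-index frames
#' (0, 2, ...) are the green channel, carrying static baseline fluorescence
#' plus calcium transients (instant rise, exponential decay with
#' `decay_tau_s`) of green-labeled somata; odd-index frames are the red
#' channel with static fluorescence of red-labeled somata. A fraction
#' `overlap_fraction` of red somata is co-labeled green. Both channels
#' additionally see a shared smooth background texture (neuropil and
#' vascular autofluorescence, which in real tissue anchors cross-channel
#' registration even when few somata are co-labeled). Per-frame rigid
#' jitter and Gaussian noise are added. Every green neuron fires at
#' least one transient, so all simulated green cells are active cells.
#'
#' @param scene A [scene_spec()].
#' @param optics An [optics_params()] (unused geometric aberrations are
#'   not applied to session data; kept for interface symmetry).
#' @param n_frames Total interleaved frames (even).
#' @param fps Sensor frame rate in Hz; each channel runs at `fps / 2`.
#' @param seed Integer RNG seed.
#' @param dims Frame size `c(ny, nx)`.
#' @param background_amp Amplitude of the shared background texture.
#' @return A list with `stack` (an interleaved [frame_stack]), and
#'   `truth`: neuron table (id, x, y, channel in green/red/both),
#'   footprint weight matrices, per-frame shifts, and per-green-neuron
#'   transient times (s).
#' @export
generate_interleaved_session <- function(scene, optics = optics_params(),
                                         n_frames = 400, fps = 10, seed = 1,
                                         dims = c(192, 192),
                                         background_amp = 8) {
  stopifnot(inherits(scene, "scene_spec"), n_frames %% 2 == 0, fps > 0)
  ny <- dims[1]; nx <- dims[2]
  n_colab <- round(scene$overlap_fraction * scene$n_neurons_red)
  n_green_only <- scene$n_neurons_green - n_colab
  if (n_green_only < 0) {
    abort("n_neurons_green must be >= overlap_fraction * n_neurons_red.")
  }
  n_red_only <- scene$n_neurons_red - n_colab
  n_total <- n_green_only + n_red_only + n_colab

  margin <- ceiling(4 * scene$soma_radius_px) + 4
  min_dist <- 3 * scene$soma_radius_px
  sigma_fp <- scene$soma_radius_px / 1.2
  out <- with_seed(seed, {
    # Poisson-disk (dart-throwing) placement: irregular like real tissue,
    # somata at least one soma diameter apart edge to edge
    cx <- numeric(0); cy <- numeric(0)
    tries <- 0
    while (length(cx) < n_total) {
      px <- runif(1, margin, nx - margin)
      py <- runif(1, margin, ny - margin)
      if (length(cx) == 0 ||
          min((cx - px)^2 + (cy - py)^2) >= min_dist^2) {
        cx <- c(cx, px); cy <- c(cy, py)
      }
      tries <- tries + 1
      if (tries > 200000) abort("Field too small for the requested neurons.")
    }
    channel <- c(rep("green", n_green_only), rep("red", n_red_only),
                 rep("both", n_colab))
    fps_ch <- fps / 2
    n_ch <- n_frames / 2
    dur <- n_ch / fps_ch
    green_idx <- which(channel %in% c("green", "both"))
    red_idx <- which(channel %in% c("red", "both"))

    # transient times: Poisson count per green neuron, uniform times;
    # at least one event when the rate is positive (active cells only)
    events <- lapply(green_idx, function(i) {
      k <- if (scene$transient_rate_hz > 0) {
        max(1L, rpois(1, scene$transient_rate_hz * dur))
      } else 0L
      sort(runif(k, 0, dur * 0.95))
    })
    names(events) <- as.character(green_idx)

    fps_frames <- seq_len(n_ch)
    t_s <- (fps_frames - 1) / fps_ch
    traces <- vapply(seq_along(green_idx), function(j) {
      tr <- numeric(n_ch)
      for (te in events[[j]]) {
        on <- t_s >= te
        tr[on] <- tr[on] + exp(-(t_s[on] - te) / scene$decay_tau_s)
      }
      tr
    }, numeric(n_ch))  # n_ch x nG

    fp <- lapply(seq_len(n_total), function(i) {
      soma_footprint(cx[i], cy[i], sigma_fp, ny, nx)
    })
    fmat_green <- vapply(green_idx, function(i) as.vector(fp[[i]]),
                         numeric(ny * nx))
    fmat_red <- vapply(red_idx, function(i) as.vector(fp[[i]]),
                       numeric(ny * nx))

    # shared smooth background texture seen by both channels,
    # normalised so its sd equals background_amp
    bg_tex <- gaussian_blur(matrix(rnorm(ny * nx), ny, nx), 8)
    bg_tex <- as.vector(bg_tex) / sd(bg_tex) * background_amp
    amp_trans <- 80
    base_green <- 10 + bg_tex + 15 * rowSums(fmat_green)  # resting fluor.
    red_img <- 15 + bg_tex + 70 * rowSums(fmat_red)
    green_clean <- matrix(base_green, ny * nx, n_ch) +
      amp_trans * (fmat_green %*% t(traces))

    shifts <- cbind(dx = rnorm(n_frames, sd = scene$jitter_sd_px),
                    dy = rnorm(n_frames, sd = scene$jitter_sd_px))
    frames <- array(0, dim = c(ny, nx, n_frames))
    for (k in seq_len(n_frames)) {
      ch_green <- (k %% 2 == 1)           # frame index k-1 even -> green
      idx_ch <- ceiling(k / 2)
      img <- if (ch_green) matrix(green_clean[, idx_ch], ny, nx)
             else matrix(red_img, ny, nx)
      if (scene$jitter_sd_px > 0) {
        img <- fourier_shift(img, shifts[k, 1], shifts[k, 2])
      }
      if (scene$noise_sd > 0) {
        img <- img + matrix(rnorm(ny * nx, sd = scene$noise_sd), ny, nx)
      }
      frames[, , k] <- img
    }
    list(frames = frames, cx = cx, cy = cy, channel = channel, fp = fp,
         shifts = shifts, events = events, green_idx = green_idx,
         red_idx = red_idx)
  })

  truth <- list(
    neurons = tibble::tibble(id = seq_along(out$cx), x_px = out$cx,
                             y_px = out$cy, channel = out$channel),
    footprints = out$fp,
    shifts = tibble::tibble(frame = seq_len(n_frames),
                            dx = out$shifts[, 1], dy = out$shifts[, 2]),
    events_s = out$events,
    green_ids = out$green_idx, red_ids = out$red_idx,
    colabel_ids = which(out$channel == "both")
  )
  list(stack = frame_stack(out$frames, fps = fps, channel = "interleaved"),
       truth = truth)
}
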