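# Geometric calibration: grid-intersection detection, radial distortion,
# per-point optimal focus, and the Petzval field-curvature sphere.

#' Separable Gaussian blur with reflect padding
#'
#' Direct separable convolution (kernel truncated at 3 sigma), the
#' workhorse behind high-pass filtering and template construction.
#'
#' @param img Numeric matrix.
#' @param sigma Blur sigma in pixels; 0 returns the input.
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_dim <- function(m) {
    n <- nrow(m)
    idx_pad <- c(rev(seq_len(r) + 1), seq_len(n), n - seq_len(r))
    mp <- m[idx_pad, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * mp[(j - 1) + seq_len(n), ,
                                                   drop = FALSE]
    out
  }
  t(conv_dim(t(conv_dim(img))))
}

# greedy non-maximum suppression on candidate peaks
suppress_peaks <- function(xy, score, min_dist) {
  ord <- order(score, decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0 ||
        min((xy[keep, 1] - xy[i, 1])^2 + (xy[keep, 2] - xy[i, 2])^2) >=
          min_dist^2) {
      keep <- c(keep, i)
    }
  }
  sort(keep)
}

# quadratic sub-pixel refinement of a correlation peak along one axis
parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (den >= 0) return(0)  # not a proper maximum
  off <- 0.5 * (ym1 - yp1) / den
  max(min(off, 0.5), -0.5)
}

# complex 2-D similarity Procrustes: find a (scale*rotation) and t with
# p ~ a * u + t  (least squares); points as n x 2 matrices
similarity_fit <- function(u, p) {
  zu <- complex(real = u[, 1], imaginary = u[, 2])
  zp <- complex(real = p[, 1], imaginary = p[, 2])
  mu_u <- mean(zu); mu_p <- mean(zp)
  du <- zu - mu_u; dp <- zp - mu_p
  a <- sum(Conj(du) * dp) / sum(Mod(du)^2)
  t_ <- mu_p - a * mu_u
  list(a = a, t = t_)
}
apply_similarity_inv <- function(p, s) {
  z <- complex(real = p[, 1], imaginary = p[, 2])
  q <- (z - s$t) / s$a
  cbind(Re(q), Im(q))
}

#' All-in-focus projection of a focal stack
#'
#' Pixelwise maximum across the scanned depths. With a curved field no
#' single depth focuses the whole grid; in the max projection every
#' intersection appears at its own best focus, which is the right input
#' for geometric (distortion) measurements.
#'
#' @param frames List of equally sized frames.
#' @return A matrix.
#' @export
focus_projection <- function(frames) Reduce(pmax, frames)

#' Detect grid-line intersections with sub-pixel precision
#'
#' Correlates the frame with a cross-shaped template, keeps well-separated
#' correlation maxima, refines each to sub-pixel by quadratic peak
#' interpolation, then matches detections to the ideal square lattice of
#' the stated spacing after a global similarity alignment (translation,
#' rotation, scale), iterated to convergence.
#'
#' @param frame Numeric matrix showing a (bright-line) grid pattern.
#' @param spacing_um Grid spacing in object um.
#' @param optics An [optics_params()] for the pixel-to-um conversion.
#' @param line_sigma_um Template line half-width in um.
#' @return A `grid_detection` object: tibble `points` with detected and
#'   matched ideal positions (um, relative to the field centre; plus
#'   pixel coordinates) and the fitted similarity transform.
#' @export
detect_grid_intersections <- function(frame, spacing_um, optics,
                                      line_sigma_um = 1.5) {
  stopifnot(is.matrix(frame), spacing_um > 0)
  pitch <- object_pixel_um(optics)
  sp_px <- spacing_um / pitch
  ny <- nrow(frame); nx <- ncol(frame)

  # cross template: two perpendicular Gaussian ridges
  half <- floor(0.45 * sp_px)
  tpl_x <- (-half):half
  sig_px <- max(line_sigma_um / pitch, 0.8)
  ridge <- exp(-tpl_x^2 / (2 * sig_px^2))
  tpl <- outer(ridge, rep(1, length(tpl_x))) +
    outer(rep(1, length(tpl_x)), ridge)
  tpl <- tpl - mean(tpl)

  # FFT correlation (frame zero-mean), template centred
  f <- frame - mean(frame)
  big_t <- matrix(0, ny, nx)
  ctr <- c(floor(ny / 2) + 1, floor(nx / 2) + 1)
  ys <- ctr[1] + tpl_x; xs <- ctr[2] + tpl_x
  big_t[ys, xs] <- tpl
  # correlation = ifft(F * Conj(T)) with template recentred to origin
  big_t <- big_t[c(ctr[1]:ny, seq_len(ctr[1] - 1)),
                 c(ctr[2]:nx, seq_len(ctr[2] - 1))]
  cc <- Re(fft(fft(f) * Conj(fft(big_t)), inverse = TRUE)) / (ny * nx)

  # candidate maxima: above half the global max, inside a margin
  thr <- 0.35 * max(cc)
  marg <- ceiling(sp_px * 0.4)
  cand <- which(cc > thr, arr.ind = TRUE)
  cand <- cand[cand[, 1] > marg & cand[, 1] <= ny - marg &
                 cand[, 2] > marg & cand[, 2] <= nx - marg, , drop = FALSE]
  # local-maximum test against 8 neighbours
  is_max <- vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    cc[r, c] >= max(cc[(r - 1):(r + 1), (c - 1):(c + 1)])
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) < 4) abort("Fewer than 4 grid intersections found.")
  keep <- suppress_peaks(cand[, c(2, 1)], cc[cand], 0.5 * sp_px)
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) < 4) abort("Fewer than 4 grid intersections found.")

  det <- t(vapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    ox <- parabolic_offset(cc[r, c - 1], cc[r, c], cc[r, c + 1])
    oy <- parabolic_offset(cc[r - 1, c], cc[r, c], cc[r + 1, c])
    c((c - 1) + ox, (r - 1) + oy)   # 0-based pixel coords (x, y)
  }, numeric(2)))

  # to centred object um
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  p_um <- cbind((det[, 1] - cx) * pitch, (det[, 2] - cy) * pitch)

  # iterate: similarity align -> snap to lattice -> refit
  sim <- list(a = 1 + 0i, t = 0 + 0i)
  ideal <- p_um
  for (iter in 1:4) {
    q <- apply_similarity_inv(p_um, sim)
    ideal <- round(q / spacing_um) * spacing_um
    if (length(unique(complex(real = ideal[, 1],
                              imaginary = ideal[, 2]))) < 3) {
      abort("Grid alignment degenerate: detections collapse onto < 3 lattice points.")
    }
    sim <- similarity_fit(ideal, p_um)
  }
  # resolve duplicates: several detections snapped to one lattice point
  key <- paste(ideal[, 1], ideal[, 2])
  q <- apply_similarity_inv(p_um, sim)
  d2 <- rowSums((q - ideal)^2)
  ok <- !logical(nrow(ideal))
  for (k in unique(key[duplicated(key)])) {
    grp <- which(key == k)
    ok[grp[-which.min(d2[grp])]] <- FALSE
  }
  # spurious correlation peaks land far from any lattice point after
  # alignment; drop them and refit
  ok <- ok & sqrt(d2) <= 0.25 * spacing_um
  if (sum(ok) < 4) abort("Fewer than 4 grid intersections found.")
  sim <- similarity_fit(ideal[ok, , drop = FALSE], p_um[ok, , drop = FALSE])
  pts <- tibble::tibble(
    x_det_um = p_um[ok, 1], y_det_um = p_um[ok, 2],
    x_det_px = det[ok, 1], y_det_px = det[ok, 2],
    x_ideal_um = ideal[ok, 1], y_ideal_um = ideal[ok, 2]
  )
  structure(list(points = pts, similarity = sim, spacing_um = spacing_um,
                 pitch_um = pitch, dims = c(ny, nx)),
            class = "grid_detection")
}

#' @export
print.grid_detection <- function(x, ...) {
  cat(sprintf("<grid_detection> %d intersections, spacing %.1f um\n",
              nrow(x$points), x$spacing_um))
  invisible(x)
}

#' Quantify radial distortion from matched grid points
#'
#' Removes translation/rotation by a similarity (Procrustes) alignment of
#' detections onto the ideal lattice, then jointly fits scale and the
#' single-coefficient radial model `r_det = s * r_ideal * (1 + k *
#' r_ideal^2)` (linear in `s` and `s*k`), so that a pure scale change
#' yields `k = 0`. Reports the model-free per-point radial displacement
#' as well.
#'
#' @param det A `grid_detection` (>= 6 matched points).
#' @return A `distortion_profile`: tibble `profile` with `r_ideal_um`,
#'   `r_det_um`, `dr_um`, and scalar `k_hat` (um^-2) and `scale`.
#' @export
measure_distortion <- function(det) {
  stopifnot(inherits(det, "grid_detection"))
  pts <- det$points
  if (nrow(pts) < 6) abort("Need >= 6 matched points.")
  u <- cbind(pts$x_ideal_um, pts$y_ideal_um)
  p <- cbind(pts$x_det_um, pts$y_det_um)
  s <- svd(scale(u, scale = FALSE))$d
  if (s[2] < 1e-6 * s[1]) abort("Degenerate (collinear) point set.")
  sim <- similarity_fit(u, p)
  q <- apply_similarity_inv(p, sim)   # detections in ideal space, scale removed
  r_i <- sqrt(rowSums(u^2))
  r_q <- sqrt(rowSums(q^2))
  use <- r_i > 0
  # joint residual-scale + radial coefficient fit
  X <- cbind(r_i[use], r_i[use]^3)
  beta <- qr.solve(X, r_q[use])
  k_hat <- beta[2] / beta[1]
  structure(
    list(profile = tibble::tibble(r_ideal_um = r_i, r_det_um = r_q,
                                  dr_um = r_q - r_i),
         k_hat = unname(k_hat), scale = Mod(sim$a) * unname(beta[1]),
         similarity = sim),
    class = "distortion_profile"
  )
}

#' @export
print.distortion_profile <- function(x, ...) {
  cat(sprintf("<distortion_profile> k = %.3g um^-2, scale = %.4f, n = %d\n",
              x$k_hat, x$scale, nrow(x$profile)))
  invisible(x)
}

#' Optimal focal depth per grid point
#'
#' For each point, computes a sharpness score (local gradient energy in a
#' window one grid-spacing wide) at every scanned depth and locates the
#' best depth by parabolic interpolation around the score maximum. Points
#' whose score peaks at the scan boundary are flagged unreliable (their
#' true optimum may lie outside the scan) and should be excluded from
#' curvature fits.
#'
#' @param depths_um Numeric vector of scanned focal depths.
#' @param frames List of frames, one per depth.
#' @param points Data frame with `x_px`, `y_px` (0-based pixel positions).
#' @param window_px Side of the scoring window; defaults to the spacing.
#' @param optics An [optics_params()] for unit conversion of the output.
#' @return A tibble of focus points: `x_px`, `y_px`, `x_um`, `y_um`
#'   (centred object um), `z_opt_um`, `reliable`, and the per-depth score
#'   curve as a list column.
#' @export
optimal_focus_per_point <- function(depths_um, frames, points, window_px,
                                    optics) {
  stopifnot(length(depths_um) >= 3, length(frames) == length(depths_um))
  if (!"x_px" %in% names(points) && "x_det_px" %in% names(points)) {
    points <- dplyr::rename(points, x_px = "x_det_px", y_px = "y_det_px")
  }
  ny <- nrow(frames[[1]]); nx <- ncol(frames[[1]])
  half <- floor(window_px / 2)
  pitch <- object_pixel_um(optics)
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  purrr::map_dfr(seq_len(nrow(points)), function(i) {
    px <- round(points$x_px[i]) + 1  # to 1-based indices
    py <- round(points$y_px[i]) + 1
    xs <- max(1, px - half):min(nx, px + half)
    ys <- max(1, py - half):min(ny, py + half)
    score <- vapply(frames, function(fr) gradient_energy(fr[ys, xs]),
                    numeric(1))
    j <- which.max(score)
    reliable <- j > 1 && j < length(score)
    z <- if (reliable) {
      # parabola through the three depths around the argmax
      dz <- depths_um[j] +
        parabolic_offset(score[j - 1], score[j], score[j + 1]) *
          (depths_um[j + 1] - depths_um[j])
      dz
    } else depths_um[j]
    tibble::tibble(x_px = points$x_px[i], y_px = points$y_px[i],
                   x_um = (points$x_px[i] - cx) * pitch,
                   y_um = (points$y_px[i] - cy) * pitch,
                   z_opt_um = z, reliable = reliable,
                   score_curve = list(score))
  })
}

#' Fit the Petzval field-curvature sphere by linear regression
#'
#' Linearised sphere fit: with `x^2 + y^2 + z^2 = 2 x0 x + 2 y0 y +
#' 2 z0 z + d`, the centre and `d` solve an ordinary least-squares
#' problem; `radius = sqrt(d + x0^2 + y0^2 + z0^2)`. Near-coplanar point
#' sets (which cannot constrain a sphere) are rejected by a condition
#' check.
#'
#' @param points Data frame with `x_um`, `y_um`, `z_opt_um` (or `z_um`);
#'   >= 4 non-coplanar points. Rows flagged `reliable = FALSE` are
#'   dropped.
#' @param max_condition Condition-number threshold for degeneracy.
#' @return A `sphere_fit` with `center` (x0, y0, z0), `radius`,
#'   `rms_residual` (um), and `n_points`.
#' @export
fit_petzval_sphere <- function(points, max_condition = 1e8) {
  if ("reliable" %in% names(points)) points <- points[points$reliable, ]
  zc <- if ("z_opt_um" %in% names(points)) points$z_opt_um else points$z_um
  x <- points$x_um; y <- points$y_um; z <- zc
  if (length(x) < 4) abort("Need >= 4 points to fit a sphere.")
  A <- cbind(2 * x, 2 * y, 2 * z, 1)
  b <- x^2 + y^2 + z^2
  sv <- svd(A)$d
  if (sv[4] <= 0 || sv[1] / sv[4] > max_condition) {
    abort("Degenerate sphere fit: points are (near-)coplanar.")
  }
  beta <- qr.solve(A, b)
  center <- beta[1:3]
  radius <- sqrt(beta[4] + sum(center^2))
  dist <- sqrt((x - center[1])^2 + (y - center[2])^2 + (z - center[3])^2)
  structure(
    list(center = unname(center), radius = unname(radius),
         rms_residual = sqrt(mean((dist - radius)^2)),
         n_points = length(x)),
    class = "sphere_fit"
  )
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "<sphere_fit> radius = %.1f um, center = (%.1f, %.1f, %.1f), rms = %.3g um (n = %d)\n",
    x$radius, x$center[1], x$center[2], x$center[3], x$rms_residual,
    x$n_points))
  invisible(x)
}

#' @rdname fit_petzval_sphere
#' @param x A `sphere_fit`.
#' @param ... Unused.
#' @method glance sphere_fit
#' @export
glance.sphere_fit <- function(x, ...) {
  tibble::tibble(radius_um = x$radius, x0_um = x$center[1],
                 y0_um = x$center[2], z0_um = x$center[3],
                 rms_residual_um = x$rms_residual, n_points = x$n_points)
}

#' Reference focal depth of a grid scan
#'
#' The depth at which the largest number of intersections are in focus: a
#' point counts as in focus at a depth where its sharpness is at least
#' 95% of its own curve maximum.
#'
#' @param focus_points Output of [optimal_focus_per_point()].
#' @param depths_um Scanned depths.
#' @return The reference depth (um).
#' @export
reference_focal_depth <- function(focus_points, depths_um) {
  counts <- vapply(seq_along(depths_um), function(j) {
    sum(vapply(focus_points$score_curve,
               function(sc) sc[j] >= 0.95 * max(sc), logical(1)))
  }, numeric(1))
  depths_um[which.max(counts)]
}
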