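# Chromatic-aberration measurement from two-channel bead volumes.

# light separable 3-point binomial smoothing of a 3-D array, replicate edges
smooth3d <- function(vol) {
  sm_axis <- function(v, axis) {
    d <- dim(v)
    n <- d[axis]
    idx_lo <- pmax(seq_len(n) - 1, 1)
    idx_hi <- pmin(seq_len(n) + 1, n)
    if (axis == 1) (v[idx_lo, , , drop = FALSE] + 2 * v +
                      v[idx_hi, , , drop = FALSE]) / 4
    else if (axis == 2) (v[, idx_lo, , drop = FALSE] + 2 * v +
                           v[, idx_hi, , drop = FALSE]) / 4
    else (v[, , idx_lo, drop = FALSE] + 2 * v +
            v[, , idx_hi, drop = FALSE]) / 4
  }
  sm_axis(sm_axis(sm_axis(vol, 1), 2), 3)
}

# 3-D local-maximum mask over the 26-neighbourhood (replicate edges)
local_max3d <- function(vol) {
  d <- dim(vol)
  mx <- vol
  for (axis in 1:3) {
    n <- d[axis]
    idx_lo <- pmax(seq_len(n) - 1, 1)
    idx_hi <- pmin(seq_len(n) + 1, n)
    if (axis == 1) mx <- pmax(mx, mx[idx_lo, , , drop = FALSE],
                              mx[idx_hi, , , drop = FALSE])
    else if (axis == 2) mx <- pmax(mx, mx[, idx_lo, , drop = FALSE],
                                   mx[, idx_hi, , drop = FALSE])
    else mx <- pmax(mx, mx[, , idx_lo, drop = FALSE],
                    mx[, , idx_hi, drop = FALSE])
  }
  vol >= mx
}

#' Detect fluorescent beads in a 3-D volume
#'
#' Lightly smooths the volume, finds local intensity maxima above a
#' robust (median + MAD) noise threshold, enforces a minimum separation
#' (keeping the brighter bead), and refines each peak to sub-voxel
#' precision. The default refinement interpolates the (smoothed)
#' intensity profile through the peak parabolically in the log domain
#' along each axis — exact for a Gaussian bead image and unbiased by
#' window truncation; axially this is parabolic interpolation of the
#' per-plane peak brightness, the natural estimator when z is a focal
#' scan with coarse steps. An intensity-weighted centroid in a 5-voxel
#' window and the plain voxel argmax are available alternatives.
#'
#' @param volume Numeric 3-D array `[y, x, z]`.
#' @param voxel_um Length-3 voxel pitch `(dy, dx, dz)` in um.
#' @param min_separation_um Minimum centre separation; closer detections
#'   keep only the brighter one.
#' @param threshold_factor Detection threshold in robust noise sds above
#'   the background median.
#' @param refine Sub-voxel refinement: `"parabolic"` (default),
#'   `"centroid"`, or `"argmax"`.
#' @return A tibble of bead peaks: `x_um`, `y_um`, `z_um` (sub-voxel,
#'   relative to the volume corner), `x_vox`, `y_vox`, `z_vox` (integer
#'   argmax voxel) and `intensity`. May be empty.
#' @export
detect_beads <- function(volume, voxel_um, min_separation_um = 20,
                         threshold_factor = 8,
                         refine = c("parabolic", "centroid", "argmax")) {
  refine <- match.arg(refine)
  stopifnot(length(dim(volume)) == 3, length(voxel_um) == 3)
  sm <- smooth3d(volume)
  bg <- median(sm)
  noise <- mad(as.vector(sm))
  thr <- bg + threshold_factor * max(noise, 1e-12)
  cand_mask <- local_max3d(sm) & sm > thr
  cand <- which(cand_mask, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble::tibble(x_um = numeric(0), y_um = numeric(0),
                          z_um = numeric(0), x_vox = integer(0),
                          y_vox = integer(0), z_vox = integer(0),
                          intensity = numeric(0)))
  }
  vals <- sm[cand_mask]
  pos_um <- cbind((cand[, 2] - 1) * voxel_um[2],   # x
                  (cand[, 1] - 1) * voxel_um[1],   # y
                  (cand[, 3] - 1) * voxel_um[3])   # z
  keep <- suppress_peaks3d(pos_um, vals, min_separation_um)
  cand <- cand[keep, , drop = FALSE]
  vals <- vals[keep]

  d <- dim(volume)
  log_par <- function(v) {
    # sub-voxel offset from 3 samples of a (log-)parabolic peak
    if (any(v <= 0)) return(0)
    lp <- log(v)
    parabolic_offset(lp[1], lp[2], lp[3])
  }
  refined <- t(vapply(seq_len(nrow(cand)), function(i) {
    iy <- cand[i, 1]; ix <- cand[i, 2]; iz <- cand[i, 3]
    if (refine == "argmax") return(c(ix - 1, iy - 1, iz - 1))
    ys <- max(1, iy - 2):min(d[1], iy + 2)
    xs <- max(1, ix - 2):min(d[2], ix + 2)
    if (refine == "centroid") {
      zs <- max(1, iz - 2):min(d[3], iz + 2)
      w <- volume[ys, xs, zs, drop = FALSE] - bg
      w[w < 0] <- 0
      tot <- sum(w)
      if (tot <= 0) return(c(ix - 1, iy - 1, iz - 1))
      return(c(sum((xs - 1) * apply(w, 2, sum)) / tot,
               sum((ys - 1) * apply(w, 1, sum)) / tot,
               sum((zs - 1) * apply(w, 3, sum)) / tot))
    }
    xf <- ix - 1; yf <- iy - 1; zf <- iz - 1
    if (ix > 1 && ix < d[2]) {
      xf <- xf + log_par(sm[iy, (ix - 1):(ix + 1), iz] - bg)
    }
    if (iy > 1 && iy < d[1]) {
      yf <- yf + log_par(sm[(iy - 1):(iy + 1), ix, iz] - bg)
    }
    if (iz > 1 && iz < d[3]) {
      # per-plane local peak brightness around the best plane
      pk <- vapply((iz - 1):(iz + 1),
                   function(k) max(volume[ys, xs, k]) - bg, numeric(1))
      zf <- zf + log_par(pk)
    }
    c(xf, yf, zf)
  }, numeric(3)))
  tibble::tibble(
    x_um = refined[, 1] * voxel_um[2], y_um = refined[, 2] * voxel_um[1],
    z_um = refined[, 3] * voxel_um[3],
    x_vox = cand[, 2] - 1L, y_vox = cand[, 1] - 1L, z_vox = cand[, 3] - 1L,
    intensity = vals
  )
}

suppress_peaks3d <- function(pos, score, min_dist) {
  ord <- order(score, decreasing = TRUE)
  keep <- integer(0)
  for (i in ord) {
    if (length(keep) == 0 ||
        min(rowSums(sweep(pos[keep, , drop = FALSE], 2, pos[i, ])^2)) >=
          min_dist^2) {
      keep <- c(keep, i)
    }
  }
  sort(keep)
}

#' Match beads across channels
#'
#' Mutual-nearest-neighbour pairing with a distance cap: a green and a
#' red detection form a pair only if each is the other's nearest
#' neighbour and their distance is at most `max_dist_um`. The result is
#' one-to-one. When the axial chromatic offset is comparable to the
#' bead spacing, full 3-D distances mispair beads; `axes = "xy"`
#' restricts the neighbour search and the cap to the lateral plane,
#' where chromatic displacement is small.
#'
#' @param green,red Bead tables from [detect_beads()].
#' @param max_dist_um Maximum pairing distance in um.
#' @param axes `"xyz"` (default) or `"xy"` for lateral-only matching.
#' @return A tibble of pairs with both positions, per-axis offsets
#'   (red - green) and the pair distance. Zero rows if nothing matches.
#' @export
match_beads <- function(green, red, max_dist_um = 20,
                        axes = c("xyz", "xy")) {
  axes <- match.arg(axes)
  empty <- tibble::tibble(
    idx_green = integer(0), idx_red = integer(0),
    gx_um = numeric(0), gy_um = numeric(0), gz_um = numeric(0),
    rx_um = numeric(0), ry_um = numeric(0), rz_um = numeric(0),
    dx_um = numeric(0), dy_um = numeric(0), dz_um = numeric(0),
    dist_um = numeric(0))
  if (nrow(green) == 0 || nrow(red) == 0) return(empty)
  G <- as.matrix(green[, c("x_um", "y_um", "z_um")])
  R <- as.matrix(red[, c("x_um", "y_um", "z_um")])
  Gm <- if (axes == "xy") G[, 1:2, drop = FALSE] else G
  Rm <- if (axes == "xy") R[, 1:2, drop = FALSE] else R
  D <- outer(rowSums(Gm^2), rep(1, nrow(Rm))) +
    outer(rep(1, nrow(Gm)), rowSums(Rm^2)) - 2 * Gm %*% t(Rm)
  D <- sqrt(pmax(D, 0))
  nn_g <- apply(D, 1, which.min)  # nearest red for each green
  nn_r <- apply(D, 2, which.min)  # nearest green for each red
  rows <- purrr::map_dfr(seq_len(nrow(G)), function(i) {
    j <- nn_g[i]
    if (nn_r[j] == i && D[i, j] <= max_dist_um) {
      tibble::tibble(idx_green = i, idx_red = j,
                     gx_um = G[i, 1], gy_um = G[i, 2], gz_um = G[i, 3],
                     rx_um = R[j, 1], ry_um = R[j, 2], rz_um = R[j, 3],
                     dx_um = R[j, 1] - G[i, 1], dy_um = R[j, 2] - G[i, 2],
                     dz_um = R[j, 3] - G[i, 3], dist_um = D[i, j])
    } else NULL
  })
  if (nrow(rows) == 0) empty else rows
}

#' Summarise chromatic offsets over matched bead pairs
#'
#' Per-axis red-minus-green offsets with mean and sample standard
#' deviation, the convention used to report lateral and axial chromatic
#' aberration (e.g. mean +/- sd of the focal-plane difference).
#'
#' @param pairs Output of [match_beads()] (>= 1 row).
#' @return A `chromatic_summary`: `per_bead_offsets` tibble,
#'   `mean_offset` and `sd_offset` (named x/y/z vectors, um), `n_pairs`.
#'   With a single pair the sd is reported as 0 with a warning.
#' @export
chromatic_offsets <- function(pairs) {
  if (nrow(pairs) < 1) abort("No matched bead pairs.")
  off <- pairs[, c("dx_um", "dy_um", "dz_um")]
  m <- c(x = mean(off$dx_um), y = mean(off$dy_um), z = mean(off$dz_um))
  if (nrow(off) == 1) {
    warn("Single bead pair: sd undefined, reported as 0.")
    s <- c(x = 0, y = 0, z = 0)
  } else {
    s <- c(x = sd(off$dx_um), y = sd(off$dy_um), z = sd(off$dz_um))
  }
  structure(list(per_bead_offsets = tibble::as_tibble(off),
                 mean_offset = m, sd_offset = s, n_pairs = nrow(off)),
            class = "chromatic_summary")
}

#' @export
print.chromatic_summary <- function(x, ...) {
  cat(sprintf(
    "<chromatic_summary> n = %d; dx = %.2f +/- %.2f, dy = %.2f +/- %.2f, dz = %.2f +/- %.2f um\n",
    x$n_pairs, x$mean_offset[1], x$sd_offset[1], x$mean_offset[2],
    x$sd_offset[2], x$mean_offset[3], x$sd_offset[3]))
  invisible(x)
}

#' @rdname chromatic_offsets
#' @param x A `chromatic_summary`.
#' @param ... Unused.
#' @method glance chromatic_summary
#' @export
glance.chromatic_summary <- function(x, ...) {
  tibble::tibble(dx_mean_um = x$mean_offset[1], dy_mean_um = x$mean_offset[2],
                 dz_mean_um = x$mean_offset[3], dx_sd_um = x$sd_offset[1],
                 dy_sd_um = x$sd_offset[2], dz_sd_um = x$sd_offset[3],
                 n_pairs = x$n_pairs)
}
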