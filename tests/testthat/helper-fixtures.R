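# Shared fixtures and independent oracles used across test files.

# brute-force 3x3 median with reflect padding (the slow obvious way)
brute_median3x3 <- function(fr) {
  p <- rbind(fr[2, , drop = FALSE], fr, fr[nrow(fr) - 1, , drop = FALSE])
  p <- cbind(p[, 2, drop = FALSE], p, p[, ncol(p) - 1, drop = FALSE])
  out <- fr
  for (i in seq_len(nrow(fr))) for (j in seq_len(ncol(fr))) {
    out[i, j] <- median(p[i:(i + 2), j:(j + 2)])
  }
  out
}

# dense spatial-domain circular cross-correlation over integer shifts
brute_xcorr_shift <- function(frame, reference) {
  ny <- nrow(frame); nx <- ncol(frame)
  f <- frame - mean(frame); r <- reference - mean(reference)
  best <- c(0, 0); best_v <- -Inf
  roll <- function(m, dy, dx) {
    m[((seq_len(ny) - 1 - dy) %% ny) + 1, ((seq_len(nx) - 1 - dx) %% nx) + 1]
  }
  for (dy in -(ny %/% 2):(ny %/% 2 - 1)) {
    for (dx in -(nx %/% 2):(nx %/% 2 - 1)) {
      v <- sum(f * roll(r, dy, dx))
      if (v > best_v) { best_v <- v; best <- c(dx, dy) }
    }
  }
  best
}

# exhaustive optimal one-to-one assignment maximising total score
# (small problems only); returns matrix of (i, j) pairs
brute_assignment <- function(score, min_score = 0) {
  n <- nrow(score); m <- ncol(score)
  stopifnot(n <= 8)
  best <- list(v = 0, pairs = matrix(numeric(0), 0, 2))
  perm_rec <- function(i, used, pairs, v) {
    if (i > n) {
      if (v > best$v) best <<- list(v = v, pairs = pairs)
      return()
    }
    perm_rec(i + 1, used, pairs, v)  # leave row i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && score[i, j] >= min_score) {
        used[j] <- TRUE
        perm_rec(i + 1, used, rbind(pairs, c(i, j)), v + score[i, j])
        used[j] <- FALSE
      }
    }
  }
  perm_rec(1, logical(m), matrix(numeric(0), 0, 2), 0)
  best$pairs
}

# dense grid search over (b, c) with the linear harmonic subproblem:
# the independent oracle for the envelope fit
grid_search_envelope <- function(profile, omega = 66.67, b_step = 0.25) {
  x <- profile$x_um
  y <- profile$intensity - median(profile$intensity)
  sse_of <- function(b, cc) {
    e <- exp(-((x - b) / cc)^2)
    M <- cbind(e, e * cos(2 * pi * x / omega), e * sin(2 * pi * x / omega))
    fit <- stats::lm.fit(M, y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    sum((y - M %*% cf)^2)
  }
  c_grid <- seq(15, 120, by = 7.5)
  # coarse pass over the whole x-range, then fine pass around the best b
  coarse_b <- seq(min(x), max(x), by = 2)
  coarse <- expand.grid(b = coarse_b, cc = c_grid)
  sse_c <- mapply(sse_of, coarse$b, coarse$cc)
  b0 <- coarse$b[which.min(sse_c)]
  fine_b <- seq(b0 - 4, b0 + 4, by = b_step)
  fine <- expand.grid(b = fine_b, cc = c_grid)
  sse_f <- mapply(sse_of, fine$b, fine$cc)
  list(b = fine$b[which.min(sse_f)], cc = fine$cc[which.min(sse_f)],
       sse = min(sse_f))
}

# render a bright-line square grid image directly (used for rotated-grid
# tests, independent of the generator)
render_grid_image <- function(ny, nx, spacing_px, theta = 0,
                              line_sigma_px = 1.2, amp = 80, base = 20) {
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2
  X <- matrix(rep(0:(nx - 1), each = ny), ny) - cx
  Y <- matrix(rep(0:(ny - 1), nx), ny) - cy
  xr <- cos(theta) * X + sin(theta) * Y
  yr <- -sin(theta) * X + cos(theta) * Y
  dline <- function(u) abs((u + spacing_px / 2) %% spacing_px - spacing_px / 2)
  base + amp * (exp(-dline(xr)^2 / (2 * line_sigma_px^2)) +
                  exp(-dline(yr)^2 / (2 * line_sigma_px^2)))
}

# synthetic neural map: gaussian footprints at given centres
make_map <- function(centers, dims = c(96, 96), sigma = 2.5,
                     labels = seq_len(nrow(centers)), channel = "red",
                     ref_seed = 1) {
  fps <- lapply(seq_len(nrow(centers)), function(i) {
    w <- duoscope:::soma_footprint(centers[i, 1], centers[i, 2], sigma,
                                   dims[1], dims[2])
    duoscope:::crop_to_footprint(w, labels[i], dims)
  })
  ref <- Reduce(`+`, lapply(fps, duoscope:::footprint_image))
  set.seed(ref_seed)
  ref <- ref * 70 + duoscope:::gaussian_blur(matrix(rnorm(prod(dims)),
                                                    dims[1]), 6) * 5
  neural_map(fps, ref, channel = channel)
}
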