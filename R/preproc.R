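# Per-frame preprocessing: de-interleaving, 3x3 median filtering, and
# Fourier-based rigid registration / motion correction.

# centred DFT frequencies, cycles per sample
fft_freq <- function(n) {
  k <- 0:(n - 1)
  ((k + floor(n / 2)) %% n - floor(n / 2)) / n
}

#' Shift an image by a (possibly fractional) translation
#'
#' Spectral (Fourier) shifting: `out(y, x) = img(y - dy, x - dx)` with
#' periodic boundary handling. Exact for integer shifts; band-limited
#' interpolation for fractional ones.
#'
#' @param img Numeric matrix.
#' @param dx,dy Shift in pixels along x (columns) and y (rows).
#' @return Shifted numeric matrix.
#' @export
fourier_shift <- function(img, dx, dy) {
  ny <- nrow(img); nx <- ncol(img)
  fy <- fft_freq(ny); fx <- fft_freq(nx)
  phase <- exp(-2i * pi * (outer(fy * dy, fx * dx, `+`)))
  Re(fft(fft(img) * phase, inverse = TRUE)) / (ny * nx)
}

#' Split an interleaved dual-channel stream into channel videos
#'
#' In alternating-illumination acquisition consecutive sensor frames come
#' from different excitation channels; each channel video runs at half the
#' sensor frame rate.
#'
#' @param stack An interleaved [frame_stack] with >= 2 frames.
#' @param phase `"green_first"` if frame 0 (the first frame) is green,
#'   `"red_first"` otherwise.
#' @return A list with `green` and `red` [frame_stack]s.
#' @export
deinterleave <- function(stack, phase = c("green_first", "red_first")) {
  stopifnot(inherits(stack, "frame_stack"), n_frames(stack) >= 2)
  phase <- match.arg(phase)
  nt <- n_frames(stack)
  odd <- seq(1, nt, by = 2)    # frame indices 0, 2, 4, ... (0-based)
  even <- seq(2, nt, by = 2)
  first <- stack$frames[, , odd, drop = FALSE]
  second <- stack$frames[, , even, drop = FALSE]
  fps_ch <- if (is.na(stack$fps)) NA_real_ else stack$fps / 2
  mk <- function(fr, ch) frame_stack(fr, fps = fps_ch, channel = ch,
                                     pwm_percent = stack$pwm_percent,
                                     meta = stack$meta)
  if (phase == "green_first") {
    list(green = mk(first, "green"), red = mk(second, "red"))
  } else {
    list(green = mk(second, "green"), red = mk(first, "red"))
  }
}

#' Re-interleave two channel videos
#'
#' Inverse of [deinterleave()]: alternates frames starting with the phase
#' channel.
#'
#' @param green,red [frame_stack]s of equal length and size.
#' @param phase Which channel provides frame 0.
#' @return An interleaved [frame_stack].
#' @export
interleave <- function(green, red, phase = c("green_first", "red_first")) {
  phase <- match.arg(phase)
  stopifnot(all(dim(green$frames) == dim(red$frames)))
  d <- dim(green$frames)
  out <- array(0, dim = c(d[1], d[2], 2 * d[3]))
  a <- if (phase == "green_first") green$frames else red$frames
  b <- if (phase == "green_first") red$frames else green$frames
  out[, , seq(1, 2 * d[3], by = 2)] <- a
  out[, , seq(2, 2 * d[3], by = 2)] <- b
  fps <- if (is.na(green$fps)) NA_real_ else green$fps * 2
  frame_stack(out, fps = fps, channel = "interleaved")
}

# reflect-pad a matrix by one pixel on every side
pad_reflect1 <- function(m) {
  m2 <- rbind(m[2, , drop = FALSE], m, m[nrow(m) - 1, , drop = FALSE])
  cbind(m2[, 2, drop = FALSE], m2, m2[, ncol(m2) - 1, drop = FALSE])
}

#' 3x3 median filter
#'
#' Replaces each pixel by the median of its 3x3 neighbourhood; edges are
#' handled by reflection. Implemented as a vectorised 9-input sorting
#' network, so it is exact (no histogram approximation).
#'
#' @param frame Numeric matrix, at least 3x3.
#' @return Filtered matrix of the same size.
#' @export
median3x3 <- function(frame) {
  stopifnot(is.matrix(frame), nrow(frame) >= 3, ncol(frame) >= 3)
  p <- pad_reflect1(frame)
  ny <- nrow(frame); nx <- ncol(frame)
  n9 <- vector("list", 9)
  idx <- 1
  for (dy in 0:2) for (dx in 0:2) {
    n9[[idx]] <- as.vector(p[dy + seq_len(ny), dx + seq_len(nx)])
    idx <- idx + 1
  }
  # full bubble-sort network on 9 lanes; lane 5 is the median
  for (i in 1:8) for (j in 1:(9 - i)) {
    lo <- pmin(n9[[j]], n9[[j + 1]])
    hi <- pmax(n9[[j]], n9[[j + 1]])
    n9[[j]] <- lo; n9[[j + 1]] <- hi
  }
  matrix(n9[[5]], ny, nx)
}

#' Median-filter every frame of a stack
#'
#' @param stack A [frame_stack].
#' @return The stack with [median3x3()] applied per frame.
#' @export
median_filter_stack <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  for (t in seq_len(n_frames(stack))) {
    stack$frames[, , t] <- median3x3(stack$frames[, , t])
  }
  stack
}

# signed shift from a 1-based wrapped index
wrap_shift <- function(idx, n) {
  s <- idx - 1
  ifelse(s > n / 2, s - n, s)
}

#' Estimate rigid translation between two frames
#'
#' Fourier cross-correlation: the returned `(dx, dy)` maximises the
#' circular cross-correlation of `frame` against `reference`, so that
#' `frame(x) ~ reference(x - d)`; applying `(-dx, -dy)` to `frame` aligns
#' it to `reference`. With `upsample > 1` the correlation is refined
#' around the integer peak by a locally upsampled discrete Fourier
#' transform (matrix-multiply DFT), giving sub-pixel precision of about
#' `1 / upsample` pixels.
#'
#' @param frame,reference Numeric matrices of identical size with nonzero
#'   variance.
#' @param upsample Integer upsampling factor (1 = integer-pixel).
#' @param max_shift Optional bound on |dx| and |dy| (pixels); use when
#'   the physical shift is known to be small (e.g. cross-channel
#'   registration of an optically co-aligned system) to reject spurious
#'   distant correlation peaks.
#' @return A list with `dx`, `dy` (pixels) and `peak_corr`, the
#'   normalised correlation at the peak.
#' @export
register_translation <- function(frame, reference, upsample = 1,
                                 max_shift = NULL) {
  stopifnot(is.matrix(frame), is.matrix(reference),
            all(dim(frame) == dim(reference)))
  if (sd(frame) == 0 || sd(reference) == 0) {
    abort("register_translation: zero-variance input.")
  }
  ny <- nrow(frame); nx <- ncol(frame)
  f1 <- fft(reference - mean(reference))
  f2 <- fft(frame - mean(frame))
  cp <- f2 * Conj(f1)
  cc <- Re(fft(cp, inverse = TRUE)) / (ny * nx)
  if (!is.null(max_shift)) {
    sy <- abs(wrap_shift(seq_len(ny), ny)) <= max_shift
    sx <- abs(wrap_shift(seq_len(nx), nx)) <= max_shift
    cc[!sy, ] <- -Inf
    cc[, !sx] <- -Inf
  }
  pk <- which.max(cc)
  iy <- (pk - 1) %% ny + 1
  ix <- (pk - 1) %/% ny + 1
  dy <- wrap_shift(iy, ny)
  dx <- wrap_shift(ix, nx)
  peak <- cc[pk]

  if (upsample > 1) {
    # evaluate the cross-correlation on a fine grid around (dx, dy);
    # an even window keeps half-pixel shifts on the refinement grid
    win <- 2 * ceiling(0.75 * upsample)
    off_y <- dy - win / (2 * upsample)
    off_x <- dx - win / (2 * upsample)
    uy <- off_y + (0:win) / upsample
    ux <- off_x + (0:win) / upsample
    fy <- fft_freq(ny); fx <- fft_freq(nx)
    Ey <- exp(2i * pi * outer(uy, fy))          # (nwin+1) x ny
    Ex <- exp(2i * pi * outer(fx, ux))          # nx x (nwin+1)
    cc_up <- Re(Ey %*% cp %*% Ex) / (ny * nx)
    pk2 <- which.max(cc_up)
    r <- (pk2 - 1) %% nrow(cc_up) + 1
    c <- (pk2 - 1) %/% nrow(cc_up) + 1
    dy <- uy[r]; dx <- ux[c]
    peak <- cc_up[pk2]
  }
  denom <- sqrt(sum((reference - mean(reference))^2) *
                  sum((frame - mean(frame))^2))
  list(dx = dx, dy = dy, peak_corr = if (denom > 0) peak / denom else 0)
}

#' Rigid motion correction of a trial
#'
#' Estimates and removes per-frame x-y shifts. The default two-pass
#' policy registers to the first frame, averages the provisionally
#' aligned frames into a sharper reference, then registers all original
#' frames to that reference. Fractional shifts are applied by spectral
#' shifting; `mode = "integer"` rounds shifts and uses exact circular
#' rolls.
#'
#' @param stack A [frame_stack].
#' @param reference_policy `"two_pass"` or `"first_frame"`.
#' @param upsample Sub-pixel registration factor (1 = integer).
#' @param mode `"subpixel"` (spectral resampling) or `"integer"`.
#' @return A list with `stack` (corrected) and `shifts`, a tibble
#'   (frame, dx, dy, peak_corr).
#' @export
motion_correct_trial <- function(stack,
                                 reference_policy = c("two_pass", "first_frame"),
                                 upsample = 10,
                                 mode = c("subpixel", "integer")) {
  stopifnot(inherits(stack, "frame_stack"), n_frames(stack) >= 1)
  reference_policy <- match.arg(reference_policy)
  mode <- match.arg(mode)
  nt <- n_frames(stack)

  register_pass <- function(ref) {
    sh <- matrix(0, nt, 3)
    for (t in seq_len(nt)) {
      r <- register_translation(stack$frames[, , t], ref, upsample = upsample)
      sh[t, ] <- c(r$dx, r$dy, r$peak_corr)
    }
    sh
  }
  apply_shifts <- function(frames, sh) {
    out <- frames
    for (t in seq_len(dim(frames)[3])) {
      dx <- sh[t, 1]; dy <- sh[t, 2]
      if (mode == "integer") { dx <- round(dx); dy <- round(dy) }
      if (dx != 0 || dy != 0) {
        out[, , t] <- fourier_shift(frames[, , t], -dx, -dy)
      }
    }
    out
  }

  ref <- stack$frames[, , 1]
  sh <- register_pass(ref)
  if (reference_policy == "two_pass" && nt > 1) {
    provisional <- apply_shifts(stack$frames, sh)
    ref <- rowMeans(provisional, dims = 2L)
    sh <- register_pass(ref)
  }
  corrected <- stack
  corrected$frames <- apply_shifts(stack$frames, sh)
  list(stack = corrected,
       shifts = tibble::tibble(frame = seq_len(nt), dx = sh[, 1],
                               dy = sh[, 2], peak_corr = sh[, 3]))
}

# gradient energy (sum of squared first differences), a simple sharpness
# score used by focus scans and motion-correction diagnostics
gradient_energy <- function(img) {
  sum(diff(img)^2) + sum(t(diff(t(img)))^2)
}
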