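# Dual-channel neuron analysis: static-channel segmentation, PNR images,
# session maps, ROI traces, and cross-channel matching by footprint
# overlap.

#' Construct a neuron footprint
#'
#' A footprint is the spatial weight image of one neuron, stored as a
#' cropped nonnegative matrix plus its offset in the full frame. Its
#' binary support (used for overlaps) is the set of pixels with weight at
#' least `support_frac` of the footprint maximum.
#'
#' @param label Identifier (scalar).
#' @param weights Nonnegative numeric matrix (cropped to the support
#'   bounding box).
#' @param x0,y0 0-based pixel offset of the crop in the full frame.
#' @param dims Full-frame size `c(ny, nx)`.
#' @param support_frac Support threshold as a fraction of max weight.
#' @return A `footprint` object.
#' @export
footprint <- function(label, weights, x0, y0, dims, support_frac = 0.5) {
  stopifnot(all(weights >= 0), any(weights > 0))
  supp <- weights >= support_frac * max(weights)
  wsum <- sum(weights)
  ys <- row(weights) - 1 + y0
  xs <- col(weights) - 1 + x0
  structure(
    list(label = label, weights = weights, x0 = x0, y0 = y0, dims = dims,
         support_frac = support_frac,
         centroid = c(x = sum(xs * weights) / wsum,
                      y = sum(ys * weights) / wsum),
         area_px = sum(supp)),
    class = "footprint"
  )
}

# linear indices (1-based, column-major in the full frame) of the support
footprint_support <- function(fp, shift = c(0, 0)) {
  supp <- fp$weights >= fp$support_frac * max(fp$weights)
  ys <- row(fp$weights)[supp] - 1 + fp$y0 + round(shift[2])
  xs <- col(fp$weights)[supp] - 1 + fp$x0 + round(shift[1])
  ok <- ys >= 0 & ys < fp$dims[1] & xs >= 0 & xs < fp$dims[2]
  (xs[ok]) * fp$dims[1] + ys[ok] + 1
}

# full-frame weight image of a footprint (dense)
footprint_image <- function(fp) {
  m <- matrix(0, fp$dims[1], fp$dims[2])
  m[fp$y0 + seq_len(nrow(fp$weights)), fp$x0 + seq_len(ncol(fp$weights))] <-
    fp$weights
  m
}

# shift a footprint by an integer number of pixels
shift_footprint <- function(fp, dx, dy) {
  fp$x0 <- fp$x0 + round(dx)
  fp$y0 <- fp$y0 + round(dy)
  fp$centroid <- fp$centroid + c(round(dx), round(dy))
  fp
}

#' Construct a neural map
#'
#' The set of footprints detected in one trial or session, together with
#' a reference image (average frame or PNR image) used for cross-map
#' registration.
#'
#' @param footprints List of [footprint()] objects with unique labels.
#' @param reference_image 2-D numeric matrix.
#' @param session_id,channel,depth_label Metadata strings.
#' @return A `neural_map`.
#' @export
neural_map <- function(footprints, reference_image, session_id = NA,
                       channel = NA, depth_label = NA) {
  labs <- vapply(footprints, function(f) as.character(f$label), character(1))
  if (anyDuplicated(labs)) abort("Footprint labels must be unique in a map.")
  structure(list(footprints = footprints, reference_image = reference_image,
                 session_id = session_id, channel = channel,
                 depth_label = depth_label),
            class = "neural_map")
}

#' @export
print.neural_map <- function(x, ...) {
  cat(sprintf("<neural_map> %d footprints, channel=%s, session=%s\n",
              length(x$footprints), x$channel, x$session_id))
  invisible(x)
}

#' @export
length.neural_map <- function(x) length(x$footprints)

# connected components of a logical matrix (8-connectivity), BFS
connected_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  ny <- nrow(mask); nx <- ncol(mask)
  nbr <- expand.grid(dy = -1:1, dx = -1:1)
  nbr <- nbr[!(nbr$dy == 0 & nbr$dx == 0), ]
  cur <- 0L
  todo <- which(mask)
  for (p in todo) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      r <- (q - 1) %% ny + 1; c <- (q - 1) %/% ny + 1
      for (j in seq_len(nrow(nbr))) {
        rr <- r + nbr$dy[j]; cc <- c + nbr$dx[j]
        if (rr >= 1 && rr <= ny && cc >= 1 && cc <= nx) {
          qq <- (cc - 1) * ny + rr
          if (mask[qq] && lab[qq] == 0L) {
            lab[qq] <- cur
            queue <- c(queue, qq)
          }
        }
      }
    }
  }
  lab
}

#' Segment somata from a static-channel average image
#'
#' The red channel carries static fluorescence, so somata are found on
#' the (high-pass filtered) average image: subtract a Gaussian-blurred
#' background, threshold at a robust noise level above the median, take
#' connected components within an area band, and keep the high-pass
#' intensities on each component as the footprint weights. A component
#' containing several well-separated intensity peaks (touching somata)
#' is split by assigning its pixels to the nearest peak.
#'
#' @param avg_image 2-D numeric matrix.
#' @param highpass_sigma_px Background blur sigma (px).
#' @param threshold_factor Threshold in robust noise sds above median.
#' @param min_area_px,max_area_px Component area band (px).
#' @param support_frac Footprint support threshold (fraction of max).
#' @param split_min_dist_px Minimum peak separation when splitting a
#'   component holding several somata (0 disables splitting).
#' @param border_px Image border excluded from detection (the high-pass
#'   filter is biased near edges); defaults to 2 sigma.
#' @param channel,session_id,depth_label Metadata for the returned map.
#' @return A [neural_map()] (possibly with zero footprints), reference
#'   image = the input average image.
#' @export
segment_static_channel <- function(avg_image, highpass_sigma_px = 6,
                                   threshold_factor = 3, min_area_px = 6,
                                   max_area_px = 400, support_frac = 0.5,
                                   split_min_dist_px = 5,
                                   border_px = 2 * highpass_sigma_px,
                                   channel = "red", session_id = NA,
                                   depth_label = NA) {
  stopifnot(is.matrix(avg_image))
  hp <- avg_image - gaussian_blur(avg_image, highpass_sigma_px)
  ny <- nrow(hp); nx <- ncol(hp)
  b <- min(border_px, floor(min(ny, nx) / 4))
  interior <- matrix(FALSE, ny, nx)
  interior[(b + 1):(ny - b), (b + 1):(nx - b)] <- TRUE
  noise <- mad(hp[interior])
  thr <- median(hp[interior]) + threshold_factor * max(noise, 1e-12)
  mask <- hp > thr & interior
  lab <- connected_components(mask)
  hp_sm <- gaussian_blur(hp, 1)
  fps <- list()
  if (max(lab) > 0) {
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l, arr.ind = TRUE)
      if (nrow(idx) < min_area_px) next
      pieces <- list(idx)
      if (split_min_dist_px > 0 && nrow(idx) > min_area_px) {
        pk <- component_peaks(hp_sm, idx, split_min_dist_px)
        if (nrow(pk) > 1) {
          near <- apply(idx, 1, function(p) {
            which.min((pk[, 1] - p[1])^2 + (pk[, 2] - p[2])^2)
          })
          pieces <- lapply(seq_len(nrow(pk)),
                           function(j) idx[near == j, , drop = FALSE])
        }
      }
      for (piece in pieces) {
        if (nrow(piece) < min_area_px || nrow(piece) > max_area_px) next
        ys <- range(piece[, 1]); xs <- range(piece[, 2])
        w <- matrix(0, ys[2] - ys[1] + 1, xs[2] - xs[1] + 1)
        vals <- hp[piece]
        w[cbind(piece[, 1] - ys[1] + 1, piece[, 2] - xs[1] + 1)] <-
          pmax(vals, 0)
        if (all(w == 0)) next
        fps[[length(fps) + 1]] <- footprint(
          label = length(fps) + 1L, weights = w, x0 = xs[1] - 1,
          y0 = ys[1] - 1, dims = dim(avg_image),
          support_frac = support_frac)
      }
    }
  }
  neural_map(fps, avg_image, session_id = session_id, channel = channel,
             depth_label = depth_label)
}

# local maxima of `img` inside a component (row/col index set), kept
# apart by non-maximum suppression and above 30% of the component max
component_peaks <- function(img, idx, min_dist) {
  v <- img[idx]
  is_pk <- vapply(seq_len(nrow(idx)), function(i) {
    r <- idx[i, 1]; c <- idx[i, 2]
    rs <- max(1, r - 1):min(nrow(img), r + 1)
    cs <- max(1, c - 1):min(ncol(img), c + 1)
    img[r, c] >= max(img[rs, cs]) && img[r, c] >= 0.3 * max(v)
  }, logical(1))
  pk <- idx[is_pk, , drop = FALSE]
  if (nrow(pk) > 1) {
    keep <- suppress_peaks(pk[, c(2, 1)], img[pk], min_dist)
    pk <- pk[keep, , drop = FALSE]
  }
  pk
}

#' Peak-to-noise-ratio image of a video
#'
#' Per pixel, `(temporal max - temporal median) / robust noise sd` of the
#' pixel's trace; pixels carrying calcium transients light up while
#' static background stays near zero. Constant pixels are 0 by
#' convention.
#'
#' @param stack A [frame_stack] with >= 10 frames.
#' @return A 2-D numeric matrix.
#' @export
pnr_image <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"), n_frames(stack) >= 10)
  d <- dim(stack$frames)
  m <- matrix(stack$frames, d[1] * d[2], d[3])
  mx <- m[, 1]
  for (t in 2:d[3]) mx <- pmax(mx, m[, t])
  med <- apply(m, 1, median)
  noise <- apply(abs(m - med), 1, median) * 1.4826
  pnr <- ifelse(noise > 0, (mx - med) / noise, 0)
  matrix(pnr, d[1], d[2])
}

#' Segment active neurons from the green channel via its PNR image
#'
#' Convenience detector: [pnr_image()] followed by
#' [segment_static_channel()] on the PNR image. A simple stand-in for
#' matrix-factorisation source extraction that suffices when somata are
#' spatially separated; externally produced footprints can be used
#' instead wherever a [neural_map()] is accepted.
#'
#' @param stack Green-channel [frame_stack].
#' @inheritParams segment_static_channel
#' @return A [neural_map()] whose reference image is the average frame.
#' @export
segment_active_channel <- function(stack, highpass_sigma_px = 6,
                                   threshold_factor = 3, min_area_px = 6,
                                   max_area_px = 400, support_frac = 0.5,
                                   session_id = NA, depth_label = NA) {
  pnr <- pnr_image(stack)
  map <- segment_static_channel(pnr, highpass_sigma_px = highpass_sigma_px,
                                threshold_factor = threshold_factor,
                                min_area_px = min_area_px,
                                max_area_px = max_area_px,
                                support_frac = support_frac,
                                channel = "green", session_id = session_id,
                                depth_label = depth_label)
  map$reference_image <- stack_mean(stack)
  map$pnr_image <- pnr
  map
}

#' Footprint overlap fraction
#'
#' `|support_A intersect support_B| / min(|A|, |B|)` by default (a soma
#' contained in a larger soma scores 1), or intersection-over-union.
#'
#' @param fpA,fpB [footprint()]s in the same coordinate frame.
#' @param denom `"min"` or `"union"`.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(fpA, fpB, denom = c("min", "union")) {
  denom <- match.arg(denom)
  sa <- footprint_support(fpA)
  sb <- footprint_support(fpB)
  if (length(sa) == 0 || length(sb) == 0) abort("Empty footprint support.")
  inter <- length(intersect(sa, sb))
  if (denom == "min") inter / min(length(sa), length(sb))
  else inter / length(union(sa, sb))
}

#' Register one neural map onto another
#'
#' Estimates the rigid translation between the maps' reference images
#' ([register_translation()]) and shifts B's footprints into A's frame.
#'
#' Cross-channel shifts are physically small (the channels share the
#' optical path), so the correlation search is bounded by `max_shift`.
#'
#' @param mapA,mapB [neural_map()]s with equal-size reference images.
#' @param upsample Sub-pixel registration factor.
#' @param max_shift Search bound in pixels, passed to
#'   [register_translation()].
#' @return A list with `shift` (dx, dy, peak_corr) and `map`, B aligned
#'   to A.
#' @export
register_maps <- function(mapA, mapB, upsample = 10, max_shift = 16) {
  stopifnot(inherits(mapA, "neural_map"), inherits(mapB, "neural_map"))
  sh <- register_translation(mapB$reference_image, mapA$reference_image,
                             upsample = upsample, max_shift = max_shift)
  out <- mapB
  out$footprints <- lapply(mapB$footprints, shift_footprint,
                           dx = -sh$dx, dy = -sh$dy)
  out$reference_image <- fourier_shift(mapB$reference_image, -sh$dx, -sh$dy)
  list(shift = sh, map = out)
}

#' Match neurons across two co-registered maps
#'
#' Computes pairwise footprint overlap fractions, keeps candidates at or
#' above the threshold, and assigns one-to-one greedily in descending
#' overlap order; ties break by smaller centroid distance, then by label
#' order, so the result is deterministic.
#'
#' @param mapA,mapB Co-registered [neural_map()]s.
#' @param threshold Minimum overlap fraction (0.5 = the 50% criterion).
#' @param denom Overlap denominator, see [overlap_fraction()].
#' @return A `match_table`: tibble `pairs` (label_a, label_b, overlap),
#'   character vectors `unmatched_a`, `unmatched_b`, and the threshold.
#' @export
match_maps <- function(mapA, mapB, threshold = 0.5,
                       denom = c("min", "union")) {
  denom <- match.arg(denom)
  fa <- mapA$footprints; fb <- mapB$footprints
  labs_a <- vapply(fa, function(f) as.character(f$label), character(1))
  labs_b <- vapply(fb, function(f) as.character(f$label), character(1))
  cand <- NULL
  if (length(fa) && length(fb)) {
    ca <- t(vapply(fa, function(f) f$centroid, numeric(2)))
    cb <- t(vapply(fb, function(f) f$centroid, numeric(2)))
    ra <- vapply(fa, function(f) max(dim(f$weights)), numeric(1))
    rb <- vapply(fb, function(f) max(dim(f$weights)), numeric(1))
    rows <- list()
    for (i in seq_along(fa)) {
      d2 <- (cb[, 1] - ca[i, 1])^2 + (cb[, 2] - ca[i, 2])^2
      near <- which(d2 <= (ra[i] + rb)^2)
      for (j in near) {
        ov <- overlap_fraction(fa[[i]], fb[[j]], denom = denom)
        if (ov >= threshold) {
          rows[[length(rows) + 1]] <- c(i, j, ov, sqrt(d2[j]))
        }
      }
    }
    if (length(rows)) cand <- do.call(rbind, rows)
  }
  pairs <- tibble::tibble(label_a = character(0), label_b = character(0),
                          overlap = numeric(0))
  used_a <- logical(length(fa)); used_b <- logical(length(fb))
  if (!is.null(cand)) {
    ord <- order(-cand[, 3], cand[, 4], cand[, 1], cand[, 2])
    for (r in ord) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!used_a[i] && !used_b[j]) {
        used_a[i] <- TRUE; used_b[j] <- TRUE
        pairs <- dplyr::bind_rows(pairs, tibble::tibble(
          label_a = labs_a[i], label_b = labs_b[j], overlap = cand[r, 3]))
      }
    }
  }
  structure(list(pairs = pairs, unmatched_a = labs_a[!used_a],
                 unmatched_b = labs_b[!used_b], threshold = threshold),
            class = "match_table")
}

#' @export
print.match_table <- function(x, ...) {
  cat(sprintf("<match_table> %d pairs (threshold %.2f), %d/%d unmatched A/B\n",
              nrow(x$pairs), x$threshold, length(x$unmatched_a),
              length(x$unmatched_b)))
  invisible(x)
}

#' @rdname match_maps
#' @param x A `match_table`.
#' @param ... Unused.
#' @method tidy match_table
#' @export
tidy.match_table <- function(x, ...) x$pairs

#' Percentage of neurons matched across channels
#'
#' `100 * pairs / (pairs + unmatched in the denominator channel)` — e.g.
#' with the red channel as denominator, the percentage of red-labeled
#' neurons that have a green-channel match.
#'
#' @param table A `match_table`.
#' @param denominator `"channel_a"` or `"channel_b"`.
#' @return Percentage in `[0, 100]`.
#' @export
matched_percentage <- function(table, denominator = c("channel_a",
                                                      "channel_b")) {
  denominator <- match.arg(denominator)
  un <- if (denominator == "channel_a") table$unmatched_a else
    table$unmatched_b
  tot <- nrow(table$pairs) + length(un)
  if (tot == 0) abort("Empty denominator map.")
  100 * nrow(table$pairs) / tot
}

#' Build a session neural map from per-trial maps
#'
#' Aligns each trial map by its rigid shift relative to the first trial
#' (estimated from the reference images unless supplied), forms
#' cross-trial correspondences by overlap matching, and averages each
#' neuron's aligned weight image over the trials where it was detected.
#'
#' @param trial_maps List of [neural_map()]s (>= 1).
#' @param trial_shifts Optional list of `c(dx, dy)` per trial relative to
#'   trial 1; estimated by [register_translation()] when `NULL`.
#' @param threshold Overlap threshold for cross-trial identity.
#' @return A [neural_map()]; each footprint's `n_trials` records how many
#'   trials contributed.
#' @export
build_session_map <- function(trial_maps, trial_shifts = NULL,
                              threshold = 0.5) {
  stopifnot(length(trial_maps) >= 1)
  n <- length(trial_maps)
  if (is.null(trial_shifts)) {
    trial_shifts <- lapply(seq_len(n), function(i) {
      if (i == 1) c(0, 0) else {
        sh <- register_translation(trial_maps[[i]]$reference_image,
                                   trial_maps[[1]]$reference_image,
                                   upsample = 10)
        c(sh$dx, sh$dy)
      }
    })
  }
  aligned <- lapply(seq_len(n), function(i) {
    m <- trial_maps[[i]]
    m$footprints <- lapply(m$footprints, shift_footprint,
                           dx = -trial_shifts[[i]][1],
                           dy = -trial_shifts[[i]][2])
    m
  })
  dims <- dim(aligned[[1]]$reference_image)
  # accumulate: session entries hold a running weight-image sum and count
  entries <- lapply(aligned[[1]]$footprints, function(f) {
    list(img = footprint_image(f), count = 1L, support_frac = f$support_frac)
  })
  if (n > 1) for (i in 2:n) {
    cur_map <- neural_map(
      lapply(seq_along(entries), function(e) {
        img <- entries[[e]]$img / entries[[e]]$count
        crop_to_footprint(img, e, dims, entries[[e]]$support_frac)
      }),
      aligned[[1]]$reference_image)
    mt <- match_maps(cur_map, aligned[[i]], threshold = threshold)
    labs_b <- vapply(aligned[[i]]$footprints,
                     function(f) as.character(f$label), character(1))
    for (r in seq_len(nrow(mt$pairs))) {
      e <- as.integer(mt$pairs$label_a[r])
      j <- which(labs_b == mt$pairs$label_b[r])
      entries[[e]]$img <- entries[[e]]$img +
        footprint_image(aligned[[i]]$footprints[[j]])
      entries[[e]]$count <- entries[[e]]$count + 1L
    }
    for (lb in mt$unmatched_b) {
      j <- which(labs_b == lb)
      f <- aligned[[i]]$footprints[[j]]
      entries[[length(entries) + 1]] <- list(img = footprint_image(f),
                                             count = 1L,
                                             support_frac = f$support_frac)
    }
  }
  fps <- lapply(seq_along(entries), function(e) {
    fp <- crop_to_footprint(entries[[e]]$img / entries[[e]]$count, e, dims,
                            entries[[e]]$support_frac)
    fp$n_trials <- entries[[e]]$count
    fp
  })
  ref <- Reduce(`+`, lapply(aligned, function(m) m$reference_image)) / n
  neural_map(fps, ref, session_id = trial_maps[[1]]$session_id,
             channel = trial_maps[[1]]$channel,
             depth_label = trial_maps[[1]]$depth_label)
}

# crop a dense weight image back to a compact footprint
crop_to_footprint <- function(img, label, dims, support_frac = 0.5) {
  idx <- which(img > 0, arr.ind = TRUE)
  ys <- range(idx[, 1]); xs <- range(idx[, 2])
  footprint(label = label,
            weights = img[ys[1]:ys[2], xs[1]:xs[2], drop = FALSE],
            x0 = xs[1] - 1, y0 = ys[1] - 1, dims = dims,
            support_frac = support_frac)
}

#' Extract an ROI fluorescence trace
#'
#' Weight-normalised mean over the footprint support per frame, optional
#' neuropil correction from an annulus around the footprint (excluding
#' any pixel belonging to a footprint of the map), and dF/F against a
#' 20th-percentile baseline.
#'
#' @param stack A [frame_stack].
#' @param fp A [footprint()] inside the frame.
#' @param neuropil_annulus `c(inner_px, outer_px)` dilation radii.
#' @param neuropil_factor Subtraction factor (0 disables correction).
#' @param exclude_map Optional [neural_map()] whose footprint supports
#'   are excluded from the annulus.
#' @return A `trace` tibble: frame, raw, neuropil, corrected, dff, plus
#'   attributes `label` and `frame_rate`.
#' @export
roi_trace <- function(stack, fp, neuropil_annulus = c(2, 6),
                      neuropil_factor = 0, exclude_map = NULL) {
  stopifnot(inherits(stack, "frame_stack"), inherits(fp, "footprint"))
  d <- dim(stack$frames)
  stopifnot(all(fp$dims == d[1:2]))
  npix <- d[1] * d[2]
  m <- matrix(stack$frames, npix, d[3])
  wimg <- footprint_image(fp)
  supp <- which(wimg > 0)
  w <- wimg[supp] / sum(wimg[supp])
  raw <- as.numeric(crossprod(m[supp, , drop = FALSE], w))

  neuropil <- rep(0, d[3])
  if (neuropil_factor != 0) {
    dil <- function(r) {
      mask <- matrix(FALSE, d[1], d[2])
      idx <- which(wimg > 0, arr.ind = TRUE)
      for (dy in -r:r) for (dx in -r:r) {
        if (dy^2 + dx^2 > r^2) next
        ys <- pmin(pmax(idx[, 1] + dy, 1), d[1])
        xs <- pmin(pmax(idx[, 2] + dx, 1), d[2])
        mask[cbind(ys, xs)] <- TRUE
      }
      mask
    }
    ann <- dil(neuropil_annulus[2]) & !dil(neuropil_annulus[1])
    if (!is.null(exclude_map)) {
      for (f2 in exclude_map$footprints) ann[footprint_support(f2)] <- FALSE
    }
    ann_idx <- which(ann)
    if (length(ann_idx) == 0) {
      warn("Empty neuropil annulus: correction skipped.")
      neuropil_factor <- 0
    } else {
      neuropil <- colMeans(m[ann_idx, , drop = FALSE])
    }
  }
  corrected <- raw - neuropil_factor * neuropil
  f0 <- quantile(corrected, 0.2, names = FALSE)
  dff <- if (abs(f0) > 1e-12) (corrected - f0) / f0 else corrected * 0
  out <- tibble::tibble(frame = seq_len(d[3]), raw = raw,
                        neuropil = neuropil, corrected = corrected,
                        dff = dff)
  attr(out, "label") <- fp$label
  attr(out, "frame_rate") <- stack$fps
  class(out) <- c("trace", class(out))
  out
}

#' Track neurons across sessions
#'
#' Registers and matches every later session against the first; each
#' first-session neuron's chain records its matched label (or `NA`) per
#' session.
#'
#' @param session_maps List of [neural_map()]s over the same field
#'   (>= 2).
#' @param threshold Overlap threshold.
#' @param upsample Registration upsampling.
#' @param max_shift Optional registration search bound; unbounded by
#'   default since inter-session field drift can be large.
#' @return A tibble: `neuron` (session-1 label), one `session_<i>`
#'   column per session, and `n_present`.
#' @export
track_longitudinal <- function(session_maps, threshold = 0.5,
                               upsample = 10, max_shift = NULL) {
  stopifnot(length(session_maps) >= 2)
  n <- length(session_maps)
  base <- session_maps[[1]]
  labs <- vapply(base$footprints, function(f) as.character(f$label),
                 character(1))
  chains <- tibble::tibble(neuron = labs)
  chains[["session_1"]] <- labs
  for (i in 2:n) {
    reg <- register_maps(base, session_maps[[i]], upsample = upsample,
                         max_shift = max_shift)
    mt <- match_maps(base, reg$map, threshold = threshold)
    col <- rep(NA_character_, length(labs))
    col[match(mt$pairs$label_a, labs)] <- mt$pairs$label_b
    chains[[paste0("session_", i)]] <- col
  }
  chains$n_present <- rowSums(!is.na(as.matrix(
    chains[, paste0("session_", seq_len(n))])))
  chains
}
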