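test_that("static segmentation finds separated somata and ignores ramps", {
  expect_length(segment_static_channel(matrix(0, 64, 64)), 0)

  # slowly varying ramp, no somata: high-pass removes it entirely
  ramp <- outer(seq(0, 50, length.out = 80), seq(0, 30, length.out = 80), `+`)
  expect_length(segment_static_channel(ramp), 0)

  set.seed(14)
  centers <- cbind(x = rep(c(22, 45, 68), each = 3) + runif(9, -3, 3),
                   y = rep(c(22, 45, 68), times = 3) + runif(9, -3, 3))
  img <- 20 + 70 * Reduce(`+`, lapply(seq_len(9), function(i) {
    duoscope:::soma_footprint(centers[i, 1], centers[i, 2], 2.5, 90, 90)
  })) + matrix(rnorm(8100, sd = 1), 90, 90)
  map <- segment_static_channel(img)
  expect_equal(length(map), 9)
  cen <- t(vapply(map$footprints, function(f) f$centroid, numeric(2)))
  err <- vapply(seq_len(9), function(i) {
    min(sqrt((cen[, 1] - centers[i, 1])^2 + (cen[, 2] - centers[i, 2])^2))
  }, numeric(1))
  expect_lt(max(err), 1)
})

test_that("PNR images highlight transient pixels only", {
  expect_equal(pnr_image(frame_stack(array(3, dim = c(6, 6, 12)))),
               matrix(0, 6, 6))

  fr <- array(rep(1, 6 * 6 * 12), dim = c(6, 6, 12))
  set.seed(1)
  fr <- fr + array(rnorm(length(fr), sd = 0.1), dim = dim(fr))
  fr[3, 4, 7] <- fr[3, 4, 7] + 10
  pnr <- pnr_image(frame_stack(fr))
  expect_equal(which(pnr == max(pnr)), 3 + 3 * 6)
  expect_gt(max(pnr), 10 * min(pnr[pnr > 0]))
})

test_that("PNR maxima co-locate with true soma centres in generated videos", {
  sc <- scene_spec(15, 5, 0.4, noise_sd = 1.5, jitter_sd_px = 0)
  sess <- generate_interleaved_session(sc, n_frames = 120, seed = 6,
                                       dims = c(96, 96))
  g <- deinterleave(sess$stack)$green
  pnr <- pnr_image(g)
  tr <- sess$truth
  # local PNR peaks (5x5 maxima above a noise floor)
  pks <- which(pnr > 8, arr.ind = TRUE)
  is_pk <- vapply(seq_len(nrow(pks)), function(j) {
    r <- pks[j, 1]; c <- pks[j, 2]
    pnr[r, c] >= max(pnr[max(1, r - 2):min(96, r + 2),
                         max(1, c - 2):min(96, c + 2)])
  }, logical(1))
  pks <- pks[is_pk, , drop = FALSE]
  hits <- vapply(tr$green_ids, function(i) {
    any(sqrt((pks[, 2] - 1 - tr$neurons$x_px[i])^2 +
               (pks[, 1] - 1 - tr$neurons$y_px[i])^2) <= 2.5)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("overlap fraction follows the intersection-over-min definition", {
  mk <- function(x0, w) footprint("a", matrix(1, 10, w), x0, 0, c(30, 60))
  a <- mk(0, 10)
  expect_equal(overlap_fraction(a, a), 1)
  expect_equal(overlap_fraction(a, mk(20, 10)), 0)
  # |A| = 100, |B| = 60, intersection 50: 50/60
  b <- footprint("b", matrix(1, 10, 6), 5, 0, c(30, 60))
  expect_equal(overlap_fraction(a, b), 50 / 60)
  expect_equal(overlap_fraction(b, a), 50 / 60)  # symmetric
  expect_equal(overlap_fraction(a, b, denom = "union"), 50 / 110)
})

test_that("map matching is greedy, deterministic, and order-symmetric", {
  set.seed(30)
  cen <- cbind(x = runif(12, 15, 80), y = runif(12, 15, 80))
  # enforce separation
  cen <- cen[c(TRUE, diff(order(cen[, 1])) != 0), , drop = FALSE]
  mapA <- make_map(cen, dims = c(96, 96))
  expect_equal(nrow(match_maps(mapA, mapA)$pairs), nrow(cen))
  expect_true(all(match_maps(mapA, mapA)$pairs$overlap == 1))

  # jittered copy: high threshold kills all matches
  cenj <- cen + matrix(runif(length(cen), -1.5, 1.5), ncol = 2)
  mapB <- make_map(cenj, dims = c(96, 96), channel = "green")
  expect_equal(nrow(match_maps(mapA, mapB, threshold = 1)$pairs), 0)

  mt_ab <- match_maps(mapA, mapB, threshold = 0.5)
  mt_ba <- match_maps(mapB, mapA, threshold = 0.5)
  expect_equal(
    dplyr::arrange(mt_ab$pairs, label_a)[, c("label_a", "label_b")],
    dplyr::arrange(
      dplyr::rename(mt_ba$pairs, label_a = label_b, label_b = label_a),
      label_a)[, c("label_a", "label_b")])
})

test_that("matched percentage uses the requested denominator", {
  mt <- structure(list(
    pairs = tibble::tibble(label_a = c("1", "2"), label_b = c("a", "b"),
                           overlap = c(0.9, 0.8)),
    unmatched_a = c("3", "4"), unmatched_b = "c", threshold = 0.5),
    class = "match_table")
  expect_equal(matched_percentage(mt, "channel_a"), 50)
  expect_equal(matched_percentage(mt, "channel_b"), 2 / 3 * 100)

  empty <- structure(list(pairs = tibble::tibble(), unmatched_a = character(0),
                          unmatched_b = character(0), threshold = 0.5),
                     class = "match_table")
  expect_error(matched_percentage(empty), "Empty")
})

test_that("matched percentage rises monotonically with the co-label fraction", {
  pct <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    set.seed(99)
    n_red <- 12
    n_co <- round(f * n_red)
    cen_red <- cbind(x = rep(seq(12, 84, length.out = 4), 3),
                     y = rep(seq(12, 84, length.out = 3), each = 4))
    cen_grn <- rbind(cen_red[seq_len(n_co), , drop = FALSE],
                     cen_red[seq_len(n_red - n_co), , drop = FALSE] +
                       cbind(rep(9, n_red - n_co), rep(9, n_red - n_co)))
    mapR <- make_map(cen_red, dims = c(96, 96))
    mapG <- make_map(cen_grn, dims = c(96, 96), channel = "green")
    matched_percentage(match_maps(mapR, mapG, threshold = 0.5), "channel_a")
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
  expect_equal(pct[1], 0)
  expect_equal(pct[5], 100)
})

test_that("map registration realigns shifted footprints", {
  set.seed(41)
  cen <- cbind(x = runif(10, 20, 70), y = runif(10, 20, 70))
  mapA <- make_map(cen, dims = c(96, 96), ref_seed = 7)
  mt0 <- match_maps(mapA, mapA)

  # integer-shifted copy of the same field
  sh <- c(4, 1)
  mapB <- make_map(cen + matrix(sh, nrow(cen), 2, byrow = TRUE),
                   dims = c(96, 96), ref_seed = 7)
  mapB$reference_image <- fourier_shift(mapA$reference_image, sh[1], sh[2])
  reg <- register_maps(mapA, mapB)
  expect_lt(abs(reg$shift$dx - sh[1]), 0.15)
  expect_lt(abs(reg$shift$dy - sh[2]), 0.15)
  mt1 <- match_maps(mapA, reg$map)
  expect_equal(nrow(mt1$pairs), nrow(mt0$pairs))
  expect_equal(mean(mt1$pairs$overlap), mean(mt0$pairs$overlap),
               tolerance = 0.05)
})

test_that("session maps average footprints over the trials that saw them", {
  set.seed(50)
  cen <- cbind(x = c(20, 50, 75), y = c(30, 60, 20))
  trial <- make_map(cen, dims = c(96, 96))
  # single trial: the session map is that trial
  s1 <- build_session_map(list(trial), list(c(0, 0)))
  expect_equal(length(s1), 3)
  expect_equal(t(vapply(s1$footprints, function(f) f$centroid, numeric(2))),
               t(vapply(trial$footprints, function(f) f$centroid,
                        numeric(2))), tolerance = 1e-9)

  # duplicated identical trials: unchanged footprints
  s2 <- build_session_map(list(trial, trial), list(c(0, 0), c(0, 0)))
  expect_equal(length(s2), 3)
  w1 <- duoscope:::footprint_image(trial$footprints[[2]])
  w2 <- duoscope:::footprint_image(
    s2$footprints[[which.min(vapply(s2$footprints, function(f) {
      sum((f$centroid - trial$footprints[[2]]$centroid)^2)
    }, numeric(1)))]])
  expect_equal(w2, w1)

  # neuron 2 missing in trial 2: averaged over trials 1 and 3 only
  trial2 <- make_map(cen[-2, , drop = FALSE], dims = c(96, 96))
  s3 <- build_session_map(list(trial, trial2, trial),
                          list(c(0, 0), c(0, 0), c(0, 0)))
  expect_equal(length(s3), 3)
  n_tr <- vapply(s3$footprints, function(f) f$n_trials, integer(1))
  expect_setequal(n_tr, c(3L, 2L, 3L))
})

test_that("ROI traces report soma fluorescence and dF/F peaks at events", {
  # constant stack: raw trace equals the constant
  st <- frame_stack(array(5, dim = c(40, 40, 8)))
  fp <- footprint("n1", matrix(1, 5, 5), 10, 10, c(40, 40))
  tr <- roi_trace(st, fp)
  expect_equal(tr$raw, rep(5, 8))

  # soma equals background: neuropil factor 1 cancels the signal
  trc <- roi_trace(st, fp, neuropil_factor = 1)
  expect_lt(max(abs(trc$corrected)), 1e-9)

  sc <- scene_spec(4, 2, 0.5, transient_rate_hz = 0.1, noise_sd = 0.5,
                   jitter_sd_px = 0, decay_tau_s = 0.8)
  sess <- generate_interleaved_session(sc, n_frames = 240, seed = 33,
                                       dims = c(72, 72))
  g <- deinterleave(sess$stack)$green
  tru <- sess$truth
  i <- tru$green_ids[1]
  fp1 <- duoscope:::crop_to_footprint(tru$footprints[[i]], "g1", c(72, 72))
  trace <- roi_trace(g, fp1)
  # reconstruct the true activity time course
  t_s <- (seq_len(120) - 1) / 5
  truth_tr <- rowSums(vapply(tru$events_s[[as.character(i)]], function(te) {
    ifelse(t_s >= te, exp(-(t_s - te) / sc$decay_tau_s), 0)
  }, numeric(120)))
  expect_gt(cor(trace$dff, truth_tr), 0.95)
  for (te in tru$events_s[[as.character(i)]]) {
    k <- which.min(abs(t_s - te))
    win <- trace$dff[max(1, k - 1):min(120, k + 1)]
    expect_gt(max(win), 0.5 * max(trace$dff))
  }
})

test_that("longitudinal tracking follows neurons across drifting sessions", {
  set.seed(60)
  cen <- cbind(x = runif(14, 25, 70), y = runif(14, 25, 70))
  keep_sep <- function(cc) {
    ok <- rep(TRUE, nrow(cc))
    for (i in 2:nrow(cc)) {
      d <- sqrt((cc[seq_len(i - 1), 1] - cc[i, 1])^2 +
                  (cc[seq_len(i - 1), 2] - cc[i, 2])^2)
      if (min(d[ok[seq_len(i - 1)]]) < 9) ok[i] <- FALSE
    }
    cc[ok, , drop = FALSE]
  }
  cen <- keep_sep(cen)
  n <- nrow(cen)
  maps <- list(make_map(cen, dims = c(104, 104), ref_seed = 3))
  drift <- c(6, 0)
  present <- matrix(TRUE, n, 4)
  set.seed(61)
  for (s in 2:4) {
    present[, s] <- runif(n) > 0.15
    cc <- cen[present[, s], , drop = FALSE] +
      matrix(drift * (s - 1), sum(present[, s]), 2, byrow = TRUE)
    m <- make_map(cc, dims = c(104, 104), ref_seed = 3,
                  labels = which(present[, s]))
    m$reference_image <- fourier_shift(maps[[1]]$reference_image,
                                       drift[1] * (s - 1),
                                       drift[2] * (s - 1))
    maps[[s]] <- m
  }
  chains <- track_longitudinal(maps)
  expect_equal(nrow(chains), n)
  # recovered presence equals simulated presence
  got <- !is.na(as.matrix(chains[, paste0("session_", 1:4)]))
  expect_equal(mean(got == present), 1)

  # identical sessions: all chains complete
  ch2 <- track_longitudinal(list(maps[[1]], maps[[1]]))
  expect_true(all(ch2$n_present == 2))
})
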