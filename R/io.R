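# Disk interchange: multi-page TIFF stacks, trial manifests, JSON results,
# and the two end-to-end workflows (calibration; dual-channel session).

#' Write a frame stack as a 16-bit multi-page TIFF
#'
#' Intensities are clamped to `[0, 65535]` and rounded; integer-valued
#' data round-trips bit-identically through [read_stack()].
#'
#' @param stack A [frame_stack].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  pages <- lapply(seq_len(n_frames(stack)), function(t) {
    m <- stack$frames[, , t]
    pmin(pmax(round(m), 0), 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a frame stack
#'
#' @param path File path.
#' @param fps,channel,pwm_percent Metadata to attach (e.g. from a
#'   manifest row).
#' @return A [frame_stack] with intensities on the stored integer scale.
#' @export
read_stack <- function(path, fps = NA_real_, channel = "green",
                       pwm_percent = NA_real_) {
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) abort(sprintf("Failed to read TIFF '%s': %s", path,
                                      conditionMessage(e))))
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    abort(sprintf("Mixed page sizes in '%s'.", path))
  }
  frame_stack(lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    storage.mode(p) <- "double"
    p
  }), fps = fps, channel = channel, pwm_percent = pwm_percent)
}

#' Read and validate a trial manifest
#'
#' A manifest is a CSV with one row per acquired trial:
#' `trial_id, path, channel, pwm_counts` or `pwm_percent`, `fps`, and
#' optional `session_id`, `depth_label`. Raw 10-bit counts are converted
#' to percent.
#'
#' @param path Manifest CSV path.
#' @param check_paths Verify that the referenced stacks exist.
#' @return A tibble with a `pwm_percent` column guaranteed.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  mf <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("trial_id", "path", "channel", "fps")
  if (!all(need %in% names(mf))) {
    abort(sprintf("Manifest missing columns: %s",
                  paste(setdiff(need, names(mf)), collapse = ", ")))
  }
  if (!"pwm_percent" %in% names(mf)) {
    if ("pwm_counts" %in% names(mf)) {
      mf$pwm_percent <- pwm_counts_to_percent(mf$pwm_counts)
    } else mf$pwm_percent <- NA_real_
  }
  bad <- !mf$channel %in% c("green", "red", "interleaved")
  if (any(bad)) abort("Manifest channel must be green, red or interleaved.")
  ok_pwm <- is.na(mf$pwm_percent) |
    (mf$pwm_percent >= 0 & mf$pwm_percent <= 100)
  if (!all(ok_pwm)) abort("Manifest pwm_percent outside [0, 100].")
  if (check_paths) {
    dirn <- dirname(path)
    mf$path <- ifelse(file.exists(mf$path), mf$path,
                      file.path(dirn, mf$path))
    missing <- !file.exists(mf$path)
    if (any(missing)) {
      abort(sprintf("Manifest references missing files: %s",
                    paste(mf$path[missing], collapse = ", ")))
    }
  }
  mf
}

#' Default run configuration
#'
#' All tunable pipeline parameters with their defaults, the RNG seed and
#' the output directory. Round-trips losslessly through JSON.
#'
#' @param workflow `"calibration"` or `"session"`.
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Output directory.
#' @param ... Overrides for any default parameter.
#' @return A `run_config` (named list).
#' @export
run_config <- function(workflow = c("session", "calibration"), seed = 1,
                       out_dir = tempfile("duoscope_run_"), ...) {
  workflow <- match.arg(workflow)
  cfg <- list(
    workflow = workflow, seed = as.integer(seed), out_dir = out_dir,
    omega_um = 66.67, overlap_threshold = 0.5, overlap_denom = "min",
    median_kernel = 3, upsample = 10, phase = "green_first",
    highpass_sigma_px = 6, segment_threshold_factor = 3,
    min_area_px = 6, max_area_px = 400, support_frac = 0.5,
    grid_spacing_um = 25, bead_max_dist_um = 20,
    bead_min_separation_um = 20, bead_threshold_factor = 8,
    bead_match_axes = "xy"
  )
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration
#'
#' @param cfg A [run_config()].
#' @param path JSON file path.
#' @return `path` / the restored `run_config`.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "run_config")
}

#' Write a synthetic acquisition bundle to disk
#'
#' Generates a complete small synthetic data set in the on-disk layout
#' the pipeline consumes: per-trial multi-page TIFFs, a `manifest.csv`,
#' and a ground-truth JSON. The calibration bundle holds a
#' depth-of-field PWM sweep, a grid focal stack and two-channel bead
#' volumes; the session bundle holds an interleaved two-channel video.
#'
#' @param dir Output directory (created).
#' @param workflow `"calibration"` or `"session"`.
#' @param seed Integer seed.
#' @param optics An [optics_params()].
#' @param scene A [scene_spec()] (session workflow).
#' @param n_sweep Number of sweep trials (calibration workflow).
#' @param n_frames Frames per trial.
#' @param dims Frame size for the session video.
#' @return The manifest tibble, invisibly.
#' @export
simulate_bundle <- function(dir, workflow = c("session", "calibration"),
                            seed = 1, optics = optics_params(),
                            scene = scene_spec(), n_sweep = 8,
                            n_frames = 40, dims = c(96, 96)) {
  workflow <- match.arg(workflow)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  if (workflow == "calibration") {
    pwms <- seq(0, 100, length.out = n_sweep)
    for (i in seq_along(pwms)) {
      tr <- generate_dof_target_trial(optics, pwms[i], n_frames = n_frames,
                                      noise_sd = 0.5, seed = seed + i,
                                      width_px = 640, height_px = 32)
      # rescale to a 16-bit-friendly range
      tr$frames <- tr$frames * 100
      p <- file.path(dir, sprintf("dof_%02d.tif", i))
      write_stack(tr, p)
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial_id = sprintf("dof_%02d", i), path = basename(p),
        channel = "green", pwm_percent = pwms[i], fps = 10,
        session_id = "cal", depth_label = NA_character_, kind = "dof")
    }
    grid <- generate_grid_stack(optics, depth_step_um = 9.6, n_depths = 12,
                                seed = seed, width_px = 160, height_px = 160,
                                noise_sd = 0.3)
    gpath <- file.path(dir, "grid.tif")
    write_stack(frame_stack(lapply(grid$frames, function(f) f * 100)), gpath)
    write.csv(data.frame(depth_um = grid$depths_um),
              file.path(dir, "grid_depths.csv"), row.names = FALSE)
    rows[[length(rows) + 1]] <- tibble::tibble(
      trial_id = "grid", path = "grid.tif", channel = "green",
      pwm_percent = NA_real_, fps = 10, session_id = "cal",
      depth_label = "scan", kind = "grid")
    beads <- generate_bead_volumes(optics, n_beads = 5, seed = seed,
                                   vol_px = c(176, 176, 48))
    for (ch in c("green", "red")) {
      v <- beads[[ch]]
      st <- frame_stack(lapply(seq_len(dim(v)[3]),
                               function(k) v[, , k] * 500))
      p <- file.path(dir, sprintf("beads_%s.tif", ch))
      write_stack(st, p)
      rows[[length(rows) + 1]] <- tibble::tibble(
        trial_id = paste0("beads_", ch), path = basename(p), channel = ch,
        pwm_percent = NA_real_, fps = 10, session_id = "cal",
        depth_label = "zstack", kind = "beads")
    }
    truth <- list(optics = unclass(optics),
                  grid_truth = grid$truth,
                  bead_positions = beads$true_positions_um,
                  bead_voxel_um = beads$voxel_um)
  } else {
    sess <- generate_interleaved_session(scene, optics, n_frames = n_frames,
                                         fps = 10, seed = seed, dims = dims)
    p <- file.path(dir, "session.tif")
    write_stack(sess$stack, p)
    rows[[length(rows) + 1]] <- tibble::tibble(
      trial_id = "session", path = "session.tif", channel = "interleaved",
      pwm_percent = NA_real_, fps = 10, session_id = "s1",
      depth_label = NA_character_, kind = "session")
    truth <- list(neurons = sess$truth$neurons, shifts = sess$truth$shifts,
                  colabel_ids = sess$truth$colabel_ids)
  }
  mf <- dplyr::bind_rows(rows)
  write.csv(mf, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(mf)
}

#' Run an end-to-end workflow
#'
#' Executes the configured workflow on a manifest directory and writes
#' machine-readable results. The calibration workflow produces
#' `depthmodel.json`, `petzval.json` and `chroma.json`; the session
#' workflow produces `session_red_map.json`, `session_green_map.json`,
#' `matches.csv` and `shifts.csv`. A `provenance.json` (config + package
#' version) accompanies every run; wall-clock timings go to
#' `timings.log`, the only non-deterministic output. Given identical
#' config and seed the result files are byte-identical across runs.
#'
#' @param config A [run_config()].
#' @param manifest_path Path to `manifest.csv` (as written by
#'   [simulate_bundle()] or by acquisition tooling).
#' @param optics An [optics_params()] used for unit conversions.
#' @return A named list of result objects, invisibly; files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, manifest_path, optics = optics_params()) {
  stopifnot(inherits(config, "run_config"))
  mf <- read_manifest(manifest_path)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- character(0)
  tic <- function(stage, expr) {
    s <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", stage, conditionMessage(e)))
    })
    timings <<- c(timings, sprintf("%s\t%.2fs", stage,
                                   as.numeric(Sys.time() - s, units = "secs")))
    r
  }
  wj <- function(x, f) jsonlite::write_json(
    x, file.path(config$out_dir, f), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  results <- list()

  if (config$workflow == "calibration") {
    dof <- mf[mf$kind == "dof", ]
    trials <- lapply(seq_len(nrow(dof)), function(i) {
      read_stack(dof$path[i], fps = dof$fps[i], channel = dof$channel[i],
                 pwm_percent = dof$pwm_percent[i])
    })
    sweep <- tic("calibrate_focus",
                 calibrate_focal_sweep(trials, optics,
                                       omega = config$omega_um))
    wj(list(trials = sweep$trials,
            model = glance(sweep$model)), "depthmodel.json")
    results$depth_model <- sweep

    grow <- mf[mf$kind == "grid", ]
    gstack <- read_stack(grow$path[1])
    depths <- read.csv(file.path(dirname(manifest_path),
                                 "grid_depths.csv"))$depth_um
    pet <- tic("calibrate_grid", {
      frames <- lapply(seq_len(n_frames(gstack)),
                       function(k) gstack$frames[, , k])
      det <- detect_grid_intersections(focus_projection(frames),
                                       config$grid_spacing_um, optics)
      dist <- measure_distortion(det)
      fpts <- optimal_focus_per_point(
        depths, frames, det$points,
        window_px = config$grid_spacing_um / object_pixel_um(optics), optics)
      list(sphere = fit_petzval_sphere(fpts), distortion = dist,
           focus_points = fpts)
    })
    wj(list(center_um = pet$sphere$center, radius_um = pet$sphere$radius,
            rms_um = pet$sphere$rms_residual, k_hat = pet$distortion$k_hat),
       "petzval.json")
    write.csv(pet$focus_points[, c("x_um", "y_um", "z_opt_um", "reliable")],
              file.path(config$out_dir, "focus_points.csv"),
              row.names = FALSE)
    results$petzval <- pet

    bj <- function(ch) {
      row <- mf[mf$kind == "beads" & mf$channel == ch, ]
      st <- read_stack(row$path[1])
      array(st$frames, dim = dim(st$frames))
    }
    chroma <- tic("calibrate_beads", {
      voxel <- c(object_pixel_um(optics), object_pixel_um(optics), 9.6)
      g <- detect_beads(bj("green"), voxel,
                        min_separation_um = config$bead_min_separation_um,
                        threshold_factor = config$bead_threshold_factor)
      r <- detect_beads(bj("red"), voxel,
                        min_separation_um = config$bead_min_separation_um,
                        threshold_factor = config$bead_threshold_factor)
      chromatic_offsets(match_beads(g, r,
                                    max_dist_um = config$bead_max_dist_um,
                                    axes = config$bead_match_axes))
    })
    wj(glance(chroma), "chroma.json")
    results$chroma <- chroma
  } else {
    srow <- mf[mf$kind == "session", ][1, ]
    raw <- read_stack(srow$path, fps = srow$fps, channel = "interleaved")
    chans <- tic("preprocess", {
      ch <- deinterleave(raw, phase = config$phase)
      lapply(ch, function(s) {
        s <- median_filter_stack(s)
        motion_correct_trial(s, upsample = config$upsample)
      })
    })
    shifts <- dplyr::bind_rows(
      dplyr::mutate(chans$green$shifts, channel = "green"),
      dplyr::mutate(chans$red$shifts, channel = "red"))
    write.csv(shifts, file.path(config$out_dir, "shifts.csv"),
              row.names = FALSE)
    maps <- tic("segment", list(
      red = segment_static_channel(
        stack_mean(chans$red$stack),
        highpass_sigma_px = config$highpass_sigma_px,
        threshold_factor = config$segment_threshold_factor,
        min_area_px = config$min_area_px, max_area_px = config$max_area_px,
        support_frac = config$support_frac, channel = "red"),
      green = segment_active_channel(
        chans$green$stack, highpass_sigma_px = config$highpass_sigma_px,
        threshold_factor = config$segment_threshold_factor,
        min_area_px = config$min_area_px, max_area_px = config$max_area_px,
        support_frac = config$support_frac)))
    mt <- tic("match", {
      reg <- register_maps(maps$red, maps$green, upsample = config$upsample)
      match_maps(maps$red, reg$map, threshold = config$overlap_threshold,
                 denom = config$overlap_denom)
    })
    write.csv(mt$pairs, file.path(config$out_dir, "matches.csv"),
              row.names = FALSE)
    map_json <- function(m) list(
      n_footprints = length(m$footprints),
      centroids = lapply(m$footprints,
                         function(f) round(unname(f$centroid), 3)),
      areas_px = vapply(m$footprints, function(f) f$area_px, numeric(1)))
    wj(map_json(maps$red), "session_red_map.json")
    wj(map_json(maps$green), "session_green_map.json")
    wj(list(n_pairs = nrow(mt$pairs),
            matched_pct_red = matched_percentage(mt, "channel_a")),
       "match_summary.json")
    results$maps <- maps
    results$matches <- mt
  }
  # provenance records the analysis parameters only; the output location
  # is environment, not configuration, and must not break determinism
  cfg_prov <- unclass(config)
  cfg_prov$out_dir <- NULL
  cfg_txt <- jsonlite::toJSON(cfg_prov, auto_unbox = TRUE, digits = NA)
  wj(list(package = "duoscope",
          version = as.character(utils::packageVersion("duoscope")),
          config = cfg_prov,
          config_hash = sum(utf8ToInt(as.character(cfg_txt)))),
     "provenance.json")
  timings <- c(timings, sprintf("total\t%.2fs",
                                as.numeric(Sys.time() - t0, units = "secs")))
  writeLines(timings, file.path(config$out_dir, "timings.log"))
  invisible(results)
}
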