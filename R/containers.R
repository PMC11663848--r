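# Core containers: frame stacks, optics and scene descriptors.
#
# Images are numeric matrices indexed [row = y, col = x], origin top-left,
# 0-based pixel centres at (col - 1, row - 1). Stacks are 3-D arrays
# [y, x, t]. All physical quantities are micrometres unless stated.

#' Construct a frame stack
#'
#' A `frame_stack` is a 3-D numeric array `[y, x, t]` of single-channel
#' frames with acquisition metadata. It is the in-memory form of a
#' multi-page grayscale video.
#'
#' @param frames A numeric 3-D array `[y, x, t]`, a matrix (single frame),
#'   or a list of equally sized matrices.
#' @param fps Acquisition frame rate in Hz.
#' @param channel Channel label: `"green"`, `"red"` or `"interleaved"`.
#' @param pwm_percent Electrowetting-lens PWM duty cycle in percent, or
#'   `NA` when not applicable.
#' @param meta Optional named list of extra metadata.
#' @return A `frame_stack` object.
#' @export
frame_stack <- function(frames, fps = NA_real_, channel = "green",
                        pwm_percent = NA_real_, meta = list()) {
  if (is.list(frames) && !is.array(frames)) {
    stopifnot(length(frames) >= 1)
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dim(frames[[1]]), length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!(is.array(frames) && length(dim(frames)) == 3L)) {
    abort("`frames` must be a [y, x, t] array, a matrix, or a list of matrices.")
  }
  channel <- match.arg(channel, c("green", "red", "interleaved"))
  structure(
    list(frames = frames, fps = fps, channel = channel,
         pwm_percent = pwm_percent, meta = meta),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d x %d px, %d frame(s), channel=%s, fps=%s, pwm=%s%%\n",
              d[2], d[1], d[3], x$channel,
              format(x$fps), format(x$pwm_percent)))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

#' Time-average frame of a stack
#'
#' @param stack A [frame_stack].
#' @return A numeric matrix, the per-pixel mean over frames.
#' @export
stack_mean <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  rowMeans(stack$frames, dims = 2L)
}

#' Optical ground-truth / calibration parameter set
#'
#' Bundles every optical quantity the calibration stages estimate, so the
#' synthetic-data generator and the fitters share one vocabulary. Defaults
#' describe a 3.3x miniscope relayed through a 1 mm GRIN lens with an
#' electrowetting tunable lens: roughly 6.6 um of focal travel per percent
#' duty cycle across a ~770 um axial range, a strongly curved field
#' (Petzval radius ~343 um) and a large negative axial chromatic offset of
#' the red channel relative to green.
#'
#' @param pixel_size_um Sensor pixel pitch, micrometres. Object-space pixel
#'   pitch is `pixel_size_um / magnification`.
#' @param magnification Optical magnification (dimensionless).
#' @param depth_per_pwm_um Focal shift per percent PWM duty cycle (um/%).
#' @param depth_offset_um Focal depth at 0% duty cycle (um).
#' @param petzval_radius_um Field-curvature sphere radius (um).
#' @param petzval_center_um Length-3 vector, sphere centre (x, y, z) in um;
#'   by default directly above the field centre.
#' @param radial_distortion_k Radial distortion coefficient (um^-2) in
#'   `r_distorted = r_ideal * (1 + k * r_ideal^2)`.
#' @param chroma_shift_um Length-3 vector (dx, dy, dz), red-minus-green
#'   chromatic offset in um.
#' @param defocus_blur_gain Blur-sigma growth per micrometre of defocus
#'   (object-space um of sigma per um of |z - focus|).
#' @return An `optics_params` object (a validated named list).
#' @export
optics_params <- function(pixel_size_um = 4.5,
                          magnification = 3.3,
                          depth_per_pwm_um = 6.57,
                          depth_offset_um = 91.73,
                          petzval_radius_um = 343.1,
                          petzval_center_um = c(0, 0, 343.1),
                          radial_distortion_k = 0,
                          chroma_shift_um = c(0.5, 0.5, -123.7),
                          defocus_blur_gain = 0.35) {
  stopifnot(pixel_size_um > 0, magnification > 0,
            petzval_radius_um > 0, defocus_blur_gain >= 0,
            length(petzval_center_um) == 3, length(chroma_shift_um) == 3)
  structure(
    list(pixel_size_um = pixel_size_um, magnification = magnification,
         depth_per_pwm_um = depth_per_pwm_um,
         depth_offset_um = depth_offset_um,
         petzval_radius_um = petzval_radius_um,
         petzval_center_um = as.numeric(petzval_center_um),
         radial_distortion_k = radial_distortion_k,
         chroma_shift_um = as.numeric(chroma_shift_um),
         defocus_blur_gain = defocus_blur_gain),
    class = "optics_params"
  )
}

# object-space micrometres per pixel
object_pixel_um <- function(optics) optics$pixel_size_um / optics$magnification

#' Synthetic two-channel scene description
#'
#' Describes the neuron population of a synthetic interleaved session:
#' how many green-active (GCaMP-like) and red-static (tdTomato-like)
#' somata, which fraction of the red population is co-labeled green,
#' transient kinetics, imaging noise and rigid jitter.
#'
#' @param n_neurons_green Total green-channel (active) neurons.
#' @param n_neurons_red Total red-channel (static) neurons.
#' @param overlap_fraction Fraction of red neurons that also carry the
#'   green indicator, in `[0, 1]`.
#' @param soma_radius_px Soma radius in pixels.
#' @param transient_rate_hz Mean calcium-transient rate per neuron (Hz).
#' @param decay_tau_s Transient exponential decay time constant (s).
#' @param noise_sd Additive Gaussian imaging noise sd (intensity units).
#' @param jitter_sd_px Per-frame rigid-motion sd in pixels.
#' @return A `scene_spec` object.
#' @export
scene_spec <- function(n_neurons_green = 100, n_neurons_red = 40,
                       overlap_fraction = 0.9, soma_radius_px = 3,
                       transient_rate_hz = 0.15, decay_tau_s = 0.5,
                       noise_sd = 2, jitter_sd_px = 1) {
  stopifnot(n_neurons_green >= 0, n_neurons_red >= 0,
            overlap_fraction >= 0, overlap_fraction <= 1,
            decay_tau_s > 0, soma_radius_px > 0)
  structure(
    list(n_neurons_green = as.integer(n_neurons_green),
         n_neurons_red = as.integer(n_neurons_red),
         overlap_fraction = overlap_fraction,
         soma_radius_px = soma_radius_px,
         transient_rate_hz = transient_rate_hz,
         decay_tau_s = decay_tau_s, noise_sd = noise_sd,
         jitter_sd_px = jitter_sd_px),
    class = "scene_spec"
  )
}

#' Convert PWM counts (0-1023) to percent duty cycle
#'
#' The lens driver accepts a 10-bit control word; calibration tables are
#' expressed in percent.
#'
#' @param counts Numeric vector of raw counts in `[0, 1023]`.
#' @return Duty cycle(s) in percent.
#' @examples
#' pwm_counts_to_percent(c(0, 512, 1023))
#' @export
pwm_counts_to_percent <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts > 1023)) {
    abort("PWM counts must lie in [0, 1023].")
  }
  counts / 1023 * 100
}

# run an expression under a local RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
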