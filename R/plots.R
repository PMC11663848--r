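# ggplot2 autoplot methods for the fitted result types.

#' Plot an envelope fit over its line profile
#'
#' @param object An `envelope_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot envelope_fit
#' @export
autoplot.envelope_fit <- function(object, ...) {
  df <- tibble::tibble(x_um = object$x_um, intensity = object$intensity,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_um)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$intensity),
                       colour = "grey50", linewidth = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#d95f02") +
    ggplot2::geom_vline(xintercept = object$b, linetype = 2) +
    ggplot2::labs(x = "x (object um)", y = "column-average intensity",
                  title = sprintf("Envelope centre b = %.1f um", object$b))
}

#' Plot a PWM-to-depth calibration
#'
#' @param object A `depth_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot depth_model
#' @export
autoplot.depth_model <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$pwm_percent, y = .data$depth_um)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#1b9e77") +
    ggplot2::labs(
      x = "PWM duty cycle (%)", y = "focal depth (um)",
      title = sprintf("depth = %.2f pwm + %.2f,  r^2 = %.3f",
                      object$slope, object$intercept, object$r_squared))
}

#' Plot per-bead chromatic offsets
#'
#' @param object A `chromatic_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot chromatic_summary
#' @export
autoplot.chromatic_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_bead_offsets,
                              cols = dplyr::everything(),
                              names_to = "axis", values_to = "offset_um")
  long$axis <- factor(long$axis, levels = c("dx_um", "dy_um", "dz_um"),
                      labels = c("x", "y", "z"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$axis, y = .data$offset_um)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "red - green offset (um)",
                  title = sprintf("Chromatic offsets (n = %d beads)",
                                  object$n_pairs))
}

#' Plot a field-curvature fit
#'
#' Shows per-point optimal depth against radial position with the fitted
#' sphere's meridional profile.
#'
#' @param object A `sphere_fit`.
#' @param focus_points The tibble passed to [fit_petzval_sphere()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sphere_fit
#' @export
autoplot.sphere_fit <- function(object, focus_points, ...) {
  if ("reliable" %in% names(focus_points)) {
    focus_points <- focus_points[focus_points$reliable, ]
  }
  r <- sqrt((focus_points$x_um - object$center[1])^2 +
              (focus_points$y_um - object$center[2])^2)
  df <- tibble::tibble(r_um = r, z_um = focus_points$z_opt_um)
  rr <- seq(0, max(r), length.out = 100)
  curve <- tibble::tibble(
    r_um = rr, z_um = object$center[3] - sqrt(object$radius^2 - rr^2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_um, y = .data$z_um)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "#7570b3") +
    ggplot2::labs(x = "radial position (um)", y = "optimal focal depth (um)",
                  title = sprintf("Petzval radius = %.1f um", object$radius))
}

#' Plot neuron footprint centroids of one or two maps
#'
#' @param map A [neural_map()].
#' @param map_b Optional second (co-registered) map to overlay.
#' @param match Optional `match_table` to mark matched neurons.
#' @return A ggplot.
#' @export
plot_neural_map <- function(map, map_b = NULL, match = NULL) {
  cen <- function(m, ch) tibble::tibble(
    x = vapply(m$footprints, function(f) f$centroid[1], numeric(1)),
    y = vapply(m$footprints, function(f) f$centroid[2], numeric(1)),
    label = vapply(m$footprints, function(f) as.character(f$label),
                   character(1)),
    channel = ch)
  df <- cen(map, ifelse(is.na(map$channel), "A", map$channel))
  if (!is.null(map_b)) {
    df <- dplyr::bind_rows(df, cen(map_b, ifelse(is.na(map_b$channel), "B",
                                                 map_b$channel)))
  }
  df$matched <- FALSE
  if (!is.null(match)) {
    df$matched <- df$label %in% c(match$pairs$label_a, match$pairs$label_b)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$channel,
                                   shape = .data$matched)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_manual(values = c(green = "#1b9e77",
                                            red = "#d95f02", A = "#1b9e77",
                                            B = "#d95f02")) +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}
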