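# Focal-plane calibration from 45-degree depth-of-field target sweeps.
#
# The column-average profile of the line target shows the 66.67 um
# line-pair oscillation under a defocus envelope; the envelope centre b is
# the lateral position of the focused band, and with the 45-degree target
# one lateral um equals one um of depth. A linear model then maps PWM duty
# cycle to focal depth.

#' Column-average intensity profile of a trial
#'
#' Per-column mean of the time-average frame, with the x-axis converted to
#' object-space micrometres.
#'
#' @param trial A [frame_stack] (the depth-of-field target trial).
#' @param optics An [optics_params()] providing the pixel-to-um conversion.
#' @return A tibble with columns `x_um` and `intensity`.
#' @export
column_average_profile <- function(trial, optics) {
  stopifnot(inherits(trial, "frame_stack"))
  if (n_frames(trial) < 1) abort("Empty stack.")
  avg <- stack_mean(trial)
  pitch <- object_pixel_um(optics)
  tibble::tibble(x_um = (seq_len(ncol(avg)) - 1) * pitch,
                 intensity = colMeans(avg))
}

# linear subproblem: best (A0, A1, B1) and SSE for fixed envelope (b, c)
envelope_linear_fit <- function(x, y, b, c, omega) {
  e <- exp(-((x - b) / c)^2)
  M <- cbind(e, e * cos(2 * pi * x / omega), e * sin(2 * pi * x / omega))
  fit <- tryCatch(stats::lm.fit(M, y), error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit$coefficients))) {
    coefs <- rep(0, 3)
    res <- y
  } else {
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
    res <- y - M %*% coefs
  }
  list(coef = as.numeric(coefs), sse = sum(res^2))
}

#' Fit the envelope-modulated first-harmonic model to a line profile
#'
#' Fits `a * exp(-((x - b)/c)^2) * (A0 + A1 cos(2 pi x / omega) +
#' B1 sin(2 pi x / omega))` by least squares: for fixed `(b, c)` the
#' harmonic coefficients are solved linearly; `(b, c)` are found by a
#' deterministic multi-start bounded quasi-Newton search (8 equispaced
#' starts in `b`, 3 scales in `c`). `omega` is the line-pair period in
#' object um and is held fixed. The envelope centre `b` estimates the
#' focused-band position. The overall amplitude is reported as
#' `a = ||(A0, A1, B1)||` with the harmonic vector normalised to unit
#' length (the product form makes the split otherwise arbitrary).
#'
#' The model decays to zero away from focus, whereas a defocused line
#' target blurs to a uniform gray, so the profile's flat background (its
#' median) is removed before fitting (`detrend = TRUE`).
#'
#' @param profile A tibble with `x_um` and `intensity` (see
#'   [column_average_profile()]), of length >= 8.
#' @param omega Line-pair period in um; 66.67 corresponds to 15 lp/mm.
#' @param detrend Subtract the profile median before fitting.
#' @return An `envelope_fit` object with fields `a`, `b`, `c`, `A0`,
#'   `A1`, `B1`, `omega`, `sse`, plus the data and fitted values.
#' @export
fit_envelope_sinusoid <- function(profile, omega = 66.67, detrend = TRUE) {
  stopifnot(is.data.frame(profile), nrow(profile) >= 8, omega > 0)
  x <- profile$x_um
  y0 <- profile$intensity
  if (sd(y0) == 0) abort("Degenerate fit: profile has zero variance.")
  baseline <- if (detrend) median(y0) else 0
  y <- y0 - baseline
  rng <- range(x)
  span <- diff(rng)

  obj <- function(par) {
    envelope_linear_fit(x, y, par[1], exp(par[2]), omega)$sse
  }
  b_starts <- seq(rng[1] + span / 16, rng[2] - span / 16, length.out = 8)
  c_starts <- c(span / 20, span / 8, span / 3)
  best <- NULL
  for (b0 in b_starts) for (c0 in c_starts) {
    fit <- tryCatch(
      optim(c(b0, log(c0)), obj, method = "L-BFGS-B",
            lower = c(rng[1], log(span / 200)),
            upper = c(rng[2], log(2 * span)),
            control = list(factr = 1e2, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("Envelope fit failed to converge from any start.")
  b <- best$par[1]
  cw <- exp(best$par[2])
  lin <- envelope_linear_fit(x, y, b, cw, omega)
  a <- sqrt(sum(lin$coef^2))
  if (a == 0) abort("Degenerate fit: zero-amplitude solution.")
  harm <- lin$coef / a
  e <- exp(-((x - b) / cw)^2)
  fitted <- a * e * (harm[1] + harm[2] * cos(2 * pi * x / omega) +
                       harm[3] * sin(2 * pi * x / omega))
  structure(
    list(a = a, b = b, c = cw, A0 = harm[1], A1 = harm[2], B1 = harm[3],
         omega = omega, sse = lin$sse, x_um = x, intensity = y0,
         fitted = fitted + baseline, baseline = baseline),
    class = "envelope_fit"
  )
}

#' @export
print.envelope_fit <- function(x, ...) {
  cat(sprintf(
    "<envelope_fit> b = %.2f um, c = %.2f um, a = %.3g, omega = %.2f, sse = %.4g\n",
    x$b, x$c, x$a, x$omega, x$sse))
  invisible(x)
}

#' @rdname fit_envelope_sinusoid
#' @param x An `envelope_fit`.
#' @param ... Unused.
#' @method tidy envelope_fit
#' @export
tidy.envelope_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "A0", "A1", "B1", "omega"),
                 estimate = c(x$a, x$b, x$c, x$A0, x$A1, x$B1, x$omega))
}

#' Focal depth from a fitted envelope
#'
#' With the 45-degree target, one object-space micrometre of lateral
#' envelope displacement equals one micrometre of depth, so
#' `depth = (b - x_ref) * tan(45 deg) + depth_ref`.
#'
#' @param fit An `envelope_fit`.
#' @param optics An [optics_params()] (kept for interface symmetry).
#' @param x_ref Lateral reference position (um) mapped to `depth_ref`.
#' @param depth_ref Depth assigned to `x_ref` (um).
#' @return Focal depth in um.
#' @export
trial_focal_depth <- function(fit, optics = NULL, x_ref = 0, depth_ref = 0) {
  stopifnot(inherits(fit, "envelope_fit"))
  (fit$b - x_ref) * tan(pi / 4) + depth_ref
}

#' Fit the linear PWM-to-depth model
#'
#' Ordinary least squares of focal depth on duty cycle, reported as
#' `depth = slope * pwm + intercept` with the coefficient of
#' determination. A zero-variance response is reported as `r_squared = 0`
#' with a warning.
#'
#' @param points A data frame with columns `pwm_percent` and `depth_um`
#'   (>= 2 distinct duty cycles).
#' @return A `depth_model` object.
#' @export
fit_depth_model <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("pwm_percent", "depth_um") %in% names(points)))
  if (length(unique(points$pwm_percent)) < 2) {
    abort("All PWM values identical: slope undefined.")
  }
  fit <- lm(depth_um ~ pwm_percent, data = points)
  ss_tot <- sum((points$depth_um - mean(points$depth_um))^2)
  if (ss_tot == 0) {
    warn("Zero-variance depths: r_squared reported as 0.")
    r2 <- 0
  } else {
    r2 <- 1 - sum(fit$residuals^2) / ss_tot
  }
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2, n_points = nrow(points), lm = fit,
         data = tibble::as_tibble(points)),
    class = "depth_model"
  )
}

#' @export
print.depth_model <- function(x, ...) {
  cat(sprintf("<depth_model> depth = %.2f * pwm + %.2f, r^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' @rdname fit_depth_model
#' @param x A `depth_model`.
#' @param ... Unused.
#' @method tidy depth_model
#' @export
tidy.depth_model <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname fit_depth_model
#' @method glance depth_model
#' @export
glance.depth_model <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_squared = x$r_squared, n_points = x$n_points)
}

#' Calibrate a focal sweep end to end
#'
#' Fits the envelope model to every trial, converts envelope centres to
#' depths (origin: the field's mid-column at the sweep's median PWM maps
#' to depth 0 by default), and fits the PWM-to-depth line.
#'
#' @param trials A list of [frame_stack]s, each with `pwm_percent` set.
#' @param optics An [optics_params()].
#' @param omega Line-pair period in um.
#' @param origin `"mid_field"` (default) or `"absolute"` (depth = b).
#' @return A `focal_sweep` object: tibble `trials` (pwm_percent, b,
#'   depth_um) and `model`, the fitted [fit_depth_model()].
#' @export
calibrate_focal_sweep <- function(trials, optics, omega = 66.67,
                                  origin = c("mid_field", "absolute")) {
  origin <- match.arg(origin)
  stopifnot(length(trials) >= 2)
  rows <- purrr::map_dfr(trials, function(tr) {
    prof <- column_average_profile(tr, optics)
    fit <- fit_envelope_sinusoid(prof, omega = omega)
    tibble::tibble(pwm_percent = tr$pwm_percent, b = fit$b,
                   sse = fit$sse)
  })
  x_ref <- if (origin == "mid_field") {
    prof1 <- column_average_profile(trials[[1]], optics)
    mean(range(prof1$x_um))
  } else 0
  rows$depth_um <- rows$b - x_ref
  model <- fit_depth_model(rows)
  structure(list(trials = rows, model = model, x_ref_um = x_ref,
                 omega = omega),
            class = "focal_sweep")
}

#' @export
print.focal_sweep <- function(x, ...) {
  cat(sprintf("<focal_sweep> %d trials; ", nrow(x$trials)))
  print(x$model)
  invisible(x)
}
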