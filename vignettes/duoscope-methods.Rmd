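---
title: "Models and methods behind duoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind duoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duoscope)
```

`duoscope` calibrates a dual-color, focus-tunable miniscope and analyzes
its interleaved two-channel recordings. This vignette explains the
models the package fits, the choices made where the procedures were
genuinely open, and what the synthetic-data generators do and do not
emulate — and therefore what a passing test suite does and does not show
about real data.

## The focal-depth model

An electrowetting lens (EWL) changes focal power with drive duty cycle.
The calibration target is a 45°-mounted 15 lp/mm line grating: because
the target surface recedes at 1 µm of depth per object-space µm of
lateral position, the *location* of the focused band along x encodes the
focal depth. The column-average profile of a trial's time-average frame
is fit with an envelope-modulated first harmonic,

$$y(x) = a\,e^{-\left(\frac{x-b}{c}\right)^2}\,
  \big(A_0 + A_1\cos(2\pi x/\omega) + B_1\sin(2\pi x/\omega)\big),$$

with the line-pair period fixed at $\omega = 66.67$ µm (15 lp/mm). Two
interpretation choices deserve note:

* **$\omega$ is a period, not an angular frequency.** The harmonic is
  implemented as $\cos(2\pi x/\omega)$; the value 66.67 only has
  physical meaning as the 15 lp/mm object-space period in µm.
* **Baseline removal before fitting.** The model decays to zero away
  from focus, but a defocused grating blurs to a uniform gray, not to
  black: the profile carries a constant background the model cannot
  represent. `fit_envelope_sinusoid()` therefore subtracts the profile
  median first (`detrend = TRUE`). Without this the optimizer inflates
  $c$ to let the envelope chase the background and the center $b$
  becomes meaningless.

The fit is separable: for fixed $(b, c)$ the coefficients
$(aA_0, aA_1, aB_1)$ solve a linear least-squares problem, and $(b, c)$
are optimized by L-BFGS-B from a deterministic grid of 8 starts in $b$
× 3 scales in $c$ (no RNG; convergence tolerance ~1e−8 relative SSE).
Because $a$ multiplies the harmonic vector, the two are jointly
unidentifiable; the package reports $a$ as the norm of the combined
coefficients with a unit-norm harmonic vector. A profile with zero
variance raises a degenerate-fit error rather than returning noise.

Depths from a duty-cycle sweep then enter an ordinary least-squares
line, `depth = slope · pwm + intercept`, with $R^2$ reported; a
zero-variance response yields $R^2 = 0$ with a warning. The depth origin
is conventional: `calibrate_focal_sweep()` maps the field's mid-column
to depth 0 by default (`origin = "mid_field"`), or reports absolute
envelope positions (`origin = "absolute"`). Slopes and $R^2$ are
invariant to this choice; intercepts are not, which is why different
acquisition series can print very different intercepts for similar
slopes.

## Field curvature and distortion

Grid intersections are detected by correlation with a cross-shaped
template (FFT-based), refined to sub-pixel by quadratic peak
interpolation, and matched to the ideal lattice through an iterated
similarity (translation/rotation/scale) alignment; detections that land
more than a quarter spacing from any lattice point after alignment are
discarded as spurious. Detection for *geometric* measurements uses the
all-in-focus (pixelwise max) projection of the depth stack: with a
curved field no single plane focuses the whole grid, and measuring on
one plane biases outer points.

**Distortion.** After Procrustes alignment, scale and the radial
coefficient compete — a pure radial term has a nonzero mean scale over
the field — so the package refits scale and $k$ *jointly* in the
linearized model $r_{det} = s\,r_{ideal} + (sk)\,r_{ideal}^3$ and
reports $\hat k = \beta_2/\beta_1$. This keeps two desirable properties
simultaneously: a pure scale change gives $\hat k = 0$, and an injected
$k$ is recovered without the attenuation a prior scale-removal step
would cause. Per-point radial displacements are also reported model-free.

**Petzval sphere.** Per-point sharpness is gradient energy (sum of
squared first differences) in a window one grid-spacing wide; the
optimal depth interpolates parabolically around the score argmax, and
points whose score peaks at a scan boundary are flagged unreliable and
excluded (their true optimum may lie outside the scan, and keeping them
biases curvature). The sphere is fit by the linear regression
$x^2+y^2+z^2 = 2x_0x + 2y_0y + 2z_0z + d$ with
$R = \sqrt{d + x_0^2+y_0^2+z_0^2}$; near-coplanar inputs are rejected by
a condition-number check. The default synthetic grid field spans about
±230 µm so that the Petzval sag (88–230 µm on a 343 µm sphere) fills a
36-step, 9.6 µm focal ladder — the geometry in which a 36-plane scan
makes sense. This matters numerically: on such a deep cap the linear
(algebraic) fit agrees with a direct nonlinear minimization of radial
residuals to ~0.1 %, whereas on a shallow cap (sag ≪ noise × geometry)
both estimators are ill-conditioned and can disagree by several percent.
The tests therefore validate the fit in the deep-cap regime and treat
the shallow regime as out of calibration scope.

## Chromatic aberration from beads

Beads are detected in each 3-D volume by light binomial smoothing, local
maxima above a robust (median + MAD) threshold, minimum-separation
suppression keeping the brighter bead, and sub-voxel refinement. The
default refinement interpolates the smoothed intensity parabolically in
the log domain along each axis — exact for a Gaussian bead image and
free of the window-truncation bias a fixed-window centroid suffers when
the axial step (9.6 µm here) is coarse; axially this amounts to
parabolic interpolation of the per-plane peak brightness, the natural
estimator when z is a focal scan. A 5-voxel intensity-weighted centroid
(`refine = "centroid"`) and the raw voxel argmax (`refine = "argmax"`)
remain available.

Matching is mutual-nearest-neighbour, one-to-one, with a distance cap
(default 20 µm). When the axial chromatic offset is comparable to the
bead spacing — the realistic case here, with ~124 µm axial offset
against ~45 µm spacing — 3-D distances mispair beads, so the chroma
workflow matches laterally (`axes = "xy"`), where chromatic displacement
is sub-micron. Offsets are reported red − green (mean ± sd per axis); a
single pair reports sd 0 with a warning.

## Preprocessing and registration

Interleaved streams alternate channels frame by frame (frame 0 = green
by default; configurable), so each channel runs at half the sensor
rate. Every frame is 3×3 median filtered — implemented as an exact
vectorized 9-input sorting network with reflect padding — and rigidly
registered by Fourier cross-correlation. Sub-pixel refinement evaluates
the correlation on a locally upsampled grid via a matrix-multiply DFT
(precision ~1/upsample px); the window is chosen even so that half-pixel
shifts lie on the refinement grid. The sign convention: the returned
$(d_x, d_y)$ satisfies frame ≈ reference shifted by $d$, and applying
$(-d_x, -d_y)$ aligns the frame. Motion correction is two-pass by
default (register to frame 1, average, re-register to the sharper
average); fractional shifts are applied by spectral shifting, with an
integer mode for strict resampling-free correction.

An optional `max_shift` bound on the correlation search exists for
cross-channel map registration: the two channels share one optical path,
so their average images can only be offset by a few pixels, and with few
co-labeled somata the unconstrained global argmax can land on a chance
alignment of unrelated cells. Longitudinal (session-to-session)
registration is unbounded by default, since field drift across weeks can
be large.

## Segmentation, traces and matching

The red (static) channel is segmented on its high-pass filtered average
image: threshold at a robust noise level above the median, connected
components within an area band, weights = high-pass intensities on the
support. Components holding several intensity peaks (touching somata)
are split by assigning pixels to the nearest peak. A border of 2
high-pass sigmas is excluded: reflect-padded filtering is biased near
edges, and on a pure intensity ramp that bias alone would otherwise
create spurious components. Green (active) neurons use the same
segmentation applied to the peak-to-noise-ratio image
(per pixel, (temporal max − median)/robust sd), which lights up
transient-carrying pixels; this PNR-seeded detector is deliberately
simple plumbing — footprints from any external source-extraction tool
can be supplied instead wherever a `neural_map` is accepted.

Footprint overlap uses binary supports (pixels ≥ 50 % of the footprint
max, configurable) and the intersection-over-minimum denominator — the
natural reading of a soma-contained-in-soma criterion — with
intersection-over-union as an option. Matching is greedy in descending
overlap with deterministic tie-breaks (centroid distance, then label
order) above the 0.5 threshold; ROI traces are weight-normalized means
with optional annulus neuropil correction and ΔF/F against a
20th-percentile baseline.

## What the generators emulate — and what they do not

The synthetic scenes are built to make every estimator's ground truth
exact: rendered defocus follows a Gaussian blur law with
σ = `defocus_blur_gain`·|Δz| (clamped at 0.3 px), gratings are rendered
with their analytically blurred contrast, calcium transients are Poisson
events with instant rise and single-exponential decay (τ = 0.5 s
default, GCaMP6f-like), somata are Gaussian blobs placed by Poisson-disk
sampling (lattice placement was rejected: its periodicity creates
spurious registration optima real tissue does not have), and both
channels share a smooth background texture emulating neuropil and
vascular autofluorescence — which is also what anchors cross-channel
registration in real recordings when few somata are co-labeled. Every
green neuron fires at least one transient, i.e. the simulated population
is the *active* population an activity-based detector could ever see.

Defaults encode the study conditions: 6.57 µm focal travel per percent
duty above a 91.73 µm offset (8.31/376.54 and 6.13/340.35 for the
dual-channel green/red variants), 24-trial sweeps of 100-frame trials,
10 fps interleaved acquisition, a 343.1 µm Petzval radius, 36 focal
planes at 9.6 µm, 25 µm grid pitch, 15 µm beads, and a
(0.5, 0.5, −123.7) µm chromatic offset. Problem sizes in the tests
(frame heights of 24–64 px, 96–192 px session fields, 8 beads, 400-frame
sessions) were chosen as the smallest scenes in which every effect being
estimated is still well-resolved.

Not emulated: wave-optical PSF structure, vignetting, sensor noise
physics (read/shot noise, fixed-pattern), non-rigid motion,
out-of-focus neuropil contamination of traces, overlapping somata, and
indicator nonlinearity. Passing tests therefore demonstrate that the
estimators invert the stated forward models correctly and behave
sensibly under additive noise and rigid motion — not that segmentation
or matching accuracy transfers to arbitrarily crowded or aberrated real
recordings. The true blur law of an EWL + GRIN path is uncharacterized;
the Gaussian defocus model is a stand-in and is flagged as such.

## Determinism and numerical conventions

Pixels are 0-based with x = column, y = row, origin top-left; z
increases away from the objective; all physical quantities are µm.
Every generator is deterministic given (parameters, seed), restoring the
caller's RNG state afterwards. `run_pipeline()` is deterministic given
config + seed: rerunning into a different directory produces
byte-identical result files (wall-clock timings go to a separate
`timings.log`, and the provenance record deliberately excludes the
output path). Envelope fits clamp $b$ to the observed x-range, sphere
fits reject condition numbers above 1e8, and degenerate inputs (flat
profiles, empty supports, all-identical PWM values, coplanar points)
raise errors rather than returning silent garbage.
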