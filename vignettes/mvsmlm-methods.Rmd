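---
title: "Models and methods in mvsmlm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mvsmlm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvsmlm)
```

mvsmlm analyses single-molecule localization microscopy (SMLM) data
acquired on one or several CMOS/sCMOS cameras: 2D fitting on a single
camera, 3D fitting on biplane or quadplane camera sets focused at offset
axial planes, and 4-channel spectrally-resolved STORM. This vignette
documents the models the package implements, the defaults and why they
were chosen, and what the synthetic-data tests do and do not demonstrate.

## The camera noise model

Every analysis step works in photo-electrons. A raw frame in ADU is
converted by the per-pixel calibration (`camera_calibration()`,
`correct_frames()`):

$$ e_{ij} = \frac{\mathrm{ADU}_{ij} - o_{ij}}{g_{ij}}, \qquad
   \operatorname{Var}(e_{ij}) = \mu_{ij} + v_{ij}, $$

where $o$ is the offset map (ADU), $g$ the gain map (ADU/e-), $\mu$ the
expected photo-electron count and $v$ the read-noise variance map
(e-^2). Corrected frames are kept as floating point and deliberately not
clipped at zero: read noise legitimately undershoots the offset, and
clipping would bias the maximum-likelihood fits that consume these
frames. Scalar calibrations are broadcast to per-pixel maps, so cameras
calibrated with one global gain are handled identically.

## The frame simulator

`simulate_movie()` renders, per plane $p$ with transmission $t_p$ and
focal offset $z_p$,

$$ \mathrm{ADU} \sim \mathrm{Pois}\!\left(b + t_p N\,
   \mathrm{PSF}(x, y, z - z_p)\right) \cdot g + o +
   \mathcal{N}(0,\, \sqrt{v}\, g), $$

rounded to integers. This is exactly the noise model the fitter assumes,
plus the signal-splitting geometry of multi-camera setups: 50/50 for
biplane, 1/4 per camera for quadplane, dichroic fractions for the
spectral configuration (`plane_geometry()` presets: biplane planes
600 nm apart, quadplane 500 nm, spectral 100 nm). Default simulation
conditions mirror the study conditions used throughout the tests:
pixel size 108 nm, PSF width 130 nm, read noise 1.6 e- (variance
2.56 e-^2), gain 2 ADU/e-, offset 100 ADU; multiplane emitters default
to N = 3640 e- with 30 e-/pixel/plane background, 2D precision tests use
N = 1000 e- over 10 e-/pixel.

The simulator emulates Poisson photon statistics, per-pixel Gaussian
read noise, defocus, signal splitting and inter-camera affine
misalignment. It does **not** emulate dye photoswitching kinetics
(on-frames are supplied explicitly), optical aberrations beyond defocus
(the 0.79 axial rescale is applied downstream, as in practice), pixel
cross-talk, or camera nonlinearity. Passing tests therefore demonstrate
the correctness of the estimators under their stated model, not
robustness to every artefact of real microscopes.

Spectral localizations are simulated by multinomial thinning: one
Poisson photon budget split over 4 channels with the dye's expected
fractions — the physically consistent model of a single emission stream
traversing sequential dichroics. The channel-fraction signatures of real
dyes (DyLight-633, Alexa-647, CF660C, CF680) are instrument-specific and
unpublished, so synthetic signatures are user-supplied and make no claim
to match the real dyes; only the classification procedure and its
oracle properties are validated.

## PSF models

Two models share one evaluation contract (`evaluate_psf()`: per-pixel
expected photon fractions, summing to at most 1):

* **Analytic Gaussian** (`gaussian_psf()`), pixel-integrated via the
  error function, optionally with first-order defocus
  $\sigma(z) = \sigma_0\sqrt{1 + (z/d)^2}$. The defaults
  $\sigma_0 = 130$ nm and $d = 400$ nm describe a high-NA (1.4) oil
  objective near focus.
* **Measured cubic-spline PSF** (`fit_spline()`): a tensor-product
  interpolating cubic B-spline over an averaged bead z-stack, 1 knot per
  pixel laterally and one knot per z slice (50 nm steps by default —
  the paperless defaults here are choices, documented, not inferences).
  The interpolant reproduces the stack exactly at every grid point, is
  C2 between samples, and exposes analytic first derivatives (from the
  B-spline basis, not finite differences, which behave badly at knot
  boundaries) for the fitter and the Fisher-information bound.
  Spline ringing can produce small negative values; evaluation clamps
  them to a floor of $10^{-9}$ of the peak because the Poisson
  likelihood requires positive means.

`average_bead_stack()` builds the input stack the way multiplane
calibrations are done in practice: beads closer than 24 px to a
neighbour are discarded (overlapping images), beads must be visible on
every plane, each surviving bead is background-subtracted (median of its
ROI border ring, per slice), aligned to sub-pixel accuracy by fitting
its sharpest slice with the Gaussian fitter, resampled onto a centred
grid, normalized to unit in-focus signal and averaged. The resampling
uses cubic-B-spline interpolation: bilinear resampling measurably
flattens the narrow in-focus core (about 10% of the peak at typical
sub-pixel shifts), which would propagate into every spline fit.

## Detection

`significance_map()` is a matched-filter detector under the camera noise
model: the PSF-shaped filter response after local (boxcar) background
subtraction, divided by the per-pixel noise scale
$\sqrt{\sum w^2 (\hat b + v)}$. The result is in units of standard
deviations, so thresholds are directly interpretable: on pure background
the map is standard normal (verified by a null-rate test), and the
default thresholds are 8 sigma for biplane and 6 sigma for quadplane
data, where the per-plane signal is half as large.
`find_candidates()` takes local maxima above threshold, suppressing
neighbours within `min_separation` (larger value wins; ties go to the
smaller row, then column — an arbitrary but fixed rule).

## Maximum-likelihood fitting

Both fitters maximize the Poisson likelihood with the read-noise
variance folded in as an offset: data and model are shifted by $v$ and
treated as Poisson. This standard device reproduces the
Poisson-plus-Gaussian model's estimating equations to second order and
keeps the likelihood single-family.

* `fit_single_plane()`: pixel-integrated 2D Gaussian, parameters
  $(x, y, N, b, \sigma)$, all spots iterated together (vectorized
  Fisher-scoring steps with per-spot Levenberg damping).
* `fit_multiplane()`: joint fit across planes of shared
  $(x, y, z, N)$ with per-plane background and fixed transmissions;
  spline-PSF evaluation per plane, positions chained through each
  plane's affine transform. Detection runs per plane; candidates are
  mapped to the reference frame and merged within 3 px. z is
  initialized by a coarse matched-filter scan over the spline's z
  slices, N by the corresponding least-squares amplitude, backgrounds
  by the window border median.

A step is accepted only if the log-likelihood does not decrease
(damping increases tenfold otherwise), which makes likelihood ascent an
assertable invariant. Convergence is a maximum absolute parameter step
below $10^{-4}$ (px, e-, nm as applicable) within 100 iterations;
non-converged fits are flagged `failed`, never silently dropped, and
fits whose window leaves the frame are flagged `rejected`. Fits that
drive z into the spline boundary are flagged `failed` rather than
reported at the clamp. Overlapping-emitter mitigation is out of scope:
candidate windows are fitted independently.

Reported per-plane signals deserve a note: the joint fit shares one $N$
with fixed transmissions, so the `signal_p` columns are measured
per-plane least-squares amplitudes (with a free flat background) at the
fitted position. They sum to $N$ within fit tolerance on consistent
data, and a plane that received no light reports approximately zero
signal even though the shared-N model cannot.

## Precision bounds

`mortensen_crb()` evaluates the closed-form MLE bound for 2D Gaussian
fitting with uniform background by adaptive quadrature (relative
tolerance $10^{-8}$): with $\sigma_a^2 = \sigma^2 + a^2/12$ and
$\tau = 2\pi\sigma_a^2 b/(N a^2)$,

$$ \sigma_x^2 = \frac{\sigma_a^2/N}
   {-\int_0^1 \frac{t\ln t}{t + \tau}\,dt}, $$

which reduces to $\sigma_a^2/N$ as $b \to 0$. `fisher_crb()` handles
arbitrary (multi)plane PSF models by summing per-pixel Fisher
information over a finite window (15 px by default; at
$\sigma/a \approx 1.2$ the excluded contribution is negligible, and the
window is recorded in the result) with
$\theta = (x, y, z, N, b_1..b_P)$. The two calculators agree within 2%
on a parameter grid, an internal consistency check between an integral
formula and a pixel sum. Inversion uses Jacobi preconditioning so that
extreme information imbalances (background near zero) stay numerically
stable; a genuinely uninformative direction (e.g. z for a single plane
at focus) raises an error naming it. `emccd_equivalent()` encodes the
excess-noise rule — an ideal EMCCD behaves like a camera receiving half
the signal — halving both N and b, since background photons traverse
the same gain register.

`photon_cost_ratio()` compares two geometries: the multiplier on the
photon budget at which the second geometry's lateral bound matches the
first's. For quadplane (500 nm spacing, 25% per plane) versus biplane
(600 nm, 50%) at a z midway between the two nearest planes — with the
defaults above — the multiplier computes to about 1.6. Splitting light
four ways costs roughly a factor two where only two planes carry usable
signal; the value falls short of exactly 2 because under a
Gaussian-defocus model the two far planes retain some lateral
information. With background, and with PSFs whose defocused images
spread faster than a Gaussian, the multiplier moves toward 2.

## Registration

`estimate_affine()` is unweighted linear least squares on point
correspondences (at least 3, non-collinear), exact on noiseless input
and $\sim 1/\sqrt{n}$-consistent under noise; correspondences come from
`match_points()` (mutual nearest neighbours within a radius). Transforms
are stored secondary-to-reference so that every localization table
carries coordinates in one canonical frame. The coordinate convention
throughout is 0-based pixel indices with x along columns; a localization
at the centre of pixel (i, j) has x = j, y = i.

## Post-processing rules

Bead tracks seed at frame 0 and collect localizations within 2 px of the
seed; seeds are not updated (the literal first-frame rule). Tracks
missing strictly more than 10% of frames are discarded — 10 missing out
of 100 survives, 11 does not — and in paired mode a track must pass on
both cameras. Precision statistics use the unbiased (n-1) standard
deviation, converted to nm by the pixel size.

Drift correction renders consecutive segments (default 1000 frames,
20 nm bins — a balance of correlation SNR against temporal resolution at
100 Hz acquisition rates) and aligns them to the first segment by the
FFT cross-correlation peak with 3-point quadratic sub-bin interpolation,
interpolating offsets linearly between segment centres. Lateral-only and
z-included modes are both provided. `rescale_z()` applies the
first-order spherical-aberration correction (default factor 0.79),
recording the factor in the table metadata.

Spectral classification normalizes the 4 channel signals to a unit-sum
vector, then either thresholds the first moment $\sum_i i\, v_i$
(cut points at midpoints between per-dye training medians) or uses
k-means (Lloyd, k-means++-style seeded initialization, seeded restarts
on empty clusters) followed by a global rejection of the
`rejection_fraction` (default 20%) of localizations most distant from
their nearest cluster mean. Rejection is a global quantile, not
per-cluster; distances are Euclidean on the normalized vectors.

## Problem sizes and determinism

All stochastic tests run under fixed seeds, and every simulator entry
point takes a mandatory seed with bit-identical reproducibility. The
test suite uses 3000–5000 simulated spots for the 2D bound-attainment
checks, 300 frames for the biplane z-recovery check, 25 beads for the
averaging convergence check and a few thousand localizations for the
drift and spectral checks — sizes at which the Monte-Carlo error of each
asserted statistic is several times smaller than the asserted tolerance.

## Known limitations

No multi-emitter (high-density) fitting; no GPU path; no astigmatism 3D;
no field-dependent (higher-than-affine) distortion correction; no
photophysics in the simulator; spline PSFs assume a uniform z grid. The
quantitative agreement demonstrated on synthetic data bounds what can be
claimed about real acquisitions, where PSF model mismatch, overlapping
emitters and residual drift dominate the error budget.
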