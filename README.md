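# mvsmlm

Analysis of single-molecule localization microscopy (SMLM) data from
multi-camera CMOS/sCMOS setups — the configuration in which emission is
split over one, two (biplane) or four (quadplane / spectral) cameras
focused at offset axial planes. The package is aimed at microscopists
building or evaluating such instruments: it covers the full reduction
path from raw ADU movies to drift-corrected, color-assigned 3D
localization tables, plus the precision bounds needed to judge whether a
camera or geometry is good enough, and a frame simulator so every stage
can be validated without a microscope.

## What it implements

* **Camera model** — per-pixel offset/gain/read-noise calibration and
  ADU-to-photo-electron conversion; total pixel variance is
  `mean + readvar` (the sCMOS noise model).
* **Simulator** — Poisson shot noise, per-pixel Gaussian read noise,
  plane splitting (50/50, 1/4 each, dichroic fractions), defocus, bead
  z-stacks and multinomially-thinned spectral signals; seed-exact.
* **PSF models** — pixel-integrated Gaussian (with defocus) and a
  measured 3D PSF: tensor cubic B-spline over averaged bead stacks
  (24 px neighbour exclusion, sub-pixel alignment), with analytic
  derivatives.
* **Detection + fitting** — matched-filter significance maps in sigma
  units (threshold 8 for biplane, 6 for quadplane), and
  maximum-likelihood fitting under the per-pixel noise model: 2D
  Gaussian per camera, or joint multiplane fits of shared
  `(x, y, z, N)` with per-plane background through inter-camera affine
  transforms.
* **Precision bounds** — the Mortensen integral for 2D Gaussian MLE,

  `sigma_x^2 = (sigma_a^2/N) / ( -∫_0^1 t ln t / (t + tau) dt )`,
  `sigma_a^2 = sigma^2 + a^2/12`, `tau = 2 pi sigma_a^2 b / (N a^2)`,

  Fisher-information bounds for arbitrary (multi)plane PSF models, the
  EMCCD excess-noise equivalence (half the signal), and photon-cost
  comparisons between geometries.
* **Registration** — mutual-nearest-neighbour pairing and least-squares
  affine estimation between cameras; exact on clean correspondences.
* **Spectral STORM** — 4-channel relative-signal vectors, first-moment
  and k-means classification with top-20% distance rejection, cross-talk
  matrices.
* **Post-processing** — bead tracking (2 px first-frame rule, >10%
  missing-frame filter), precision statistics, drift correction by
  segment cross-correlation, the 0.79 spherical-aberration z rescale,
  and histogram/Gaussian rendering with `autoplot()` support.

## Worked example

Simulate a 50-frame biplane movie of one emitter (N = 3640 e-,
30 e-/px/plane background, 600 nm plane spacing), build a spline PSF,
fit jointly, and apply the axial rescale:

```r
library(mvsmlm)

cal  <- camera_calibration(offset = 100, gain = 2, readvar = 1.6^2,
                           shape = c(24, 24))
psf  <- gaussian_psf(130, depth = 400)
geom <- biplane_geometry(600)

spline <- local({
  zs <- seq(-900, 900, by = 50)
  stack <- array(0, c(25, 25, length(zs)))
  for (i in seq_along(zs))
    stack[, , i] <- evaluate_psf(psf, 12, 12, zs[i], window = 25,
                                 pixel_size = 108)
  fit_spline(stack, zs)
})

em     <- emitters(x = 11.5, y = 11.3, z = 150, photons = 3640,
                   on_frames = list(0:49))
movie  <- simulate_movie(em, psf, geom, cal, background = 30,
                         n_frames = 50, seed = 42)
frames <- lapply(movie, correct_frames, cal = cal)
locs   <- fit_multiplane(frames, cal, spline, geom,
                         fit_config(threshold = 8)) |> rescale_z()
glance(locs)
#> # A tibble: 1 × 6
#>       n n_converged mean_photons mean_background n_frames pixel_size
#>   <int>       <int>        <dbl>           <dbl>    <int>      <dbl>
#> 1    50          50        3636.            29.9       50        108
median(locs$z[locs$status == "converged"])   # ~118 nm = 0.79 * 150
```

All 50 detections converge; the fitted signal and background recover the
simulation's ground truth, and the rescaled median z sits at
0.79 times the true 150 nm. The matching precision bounds:

```r
mortensen_crb(N = 9100, b = 53, a = 108, sigma = 130)
#> <crb_result:mortensen> sigma_x = 1.702 nm, sigma_y = 1.702 nm

fisher_crb(spline, geom, N = 3640, b = 30, readvar = 2.56, z = 150)
#> <crb_result:fisher> sigma_x = 4.228 nm, sigma_y = 4.228 nm, sigma_z = 15.92 nm
```

The first number is the theoretical lateral precision of a bright
(9100 e-) localization on a low-noise camera — about 1.7 nm; the second
is the 3D bound for the simulated biplane conditions, which the fitter
attains in the test suite.

A thin command-line interface over the same functions ships in
`inst/cli/mvsmlm.R` (`correct`, `register`, `crb`, `classify`,
`rescale`).

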