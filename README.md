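# aberrsim

Physics-based synthetic optical aberrations for 3D fluorescence
microscopy, in R.

Deep-learning restoration of aberrated microscopy data needs paired
training examples, but matched (aberrated, aberration-free) acquisitions
are rarely available. `aberrsim` implements the computational core of a
synthetic-aberration strategy: take near-diffraction-limited volumes (in
practice, the shallow planes of a stack, or simulated phantoms), degrade
them with *known* aberrations drawn from a physically parameterized
family, and use the resulting pairs to train and benchmark restoration
methods. The package is aimed at microscopists and image-analysis
developers who want a controlled, reproducible degradation model and the
surrounding evaluation tooling without any microscope hardware.

## What it computes

**Wavefronts.** Aberrations are Zernike expansions at the pupil,
`phi(r,t) = sum_m c_m phi_m(r,t)`, ANSI-indexed, orthonormal (unit-RMS)
modes, coefficients in radians. The RMS wavefront distortion is the
coefficient norm excluding piston/tilt, `RMS_c = sqrt(sum_{m>=3} c_m^2)`.
Coefficients are sampled uniformly under per-mode bounds `|c_m| <= T_m`
and normalized either to a maximum RMS (`Omega / RMS_T`) or to an exact
RMS (`Upsilon / RMS_c`); single named modes (defocus, astigmatism, coma,
trefoil, spherical) are also available.

**Degradation.** Scalar Fourier optics synthesizes ideal and aberrated
PSFs (angular-spectrum defocus, optional Gaussian light-sheet envelope);
the ground-truth spectrum is multiplied by the modified OTF
`mOTF = FT(aPSF) / FT(iPSF)` and inverse transformed, then Poisson noise
is injected at a photon SNR defined as `sqrt(S)` with `S` the mean of
voxels above 1% of the maximum.

**Everything around it.** A seeded 3D phantom generator (dots, lines,
rings, spheres, shells); training-corpus construction with manifests and
bit-reproducible pairs; Richardson–Lucy deconvolution and preprocessing
(background subtraction, exponential depth-attenuation compensation,
time-lapse intensity renormalization); volumetric SSIM/PSNR, RMS
contrast, photon SNR and DCT-entropy sharpness; a pluggable
restoration-model contract with seam-free tiled application; and 3D
fiber/vessel orientation estimation with directional-variance statistics
in [0, 1] (0 = parallel, 1 = isotropic).

See `vignettes/aberration-engine.Rmd` for the full model description and
numerical conventions.

## Worked example

Degrade a phantom with a random 2-rad aberration at SNR 16, then restore
it with the built-in (linear) reference model:

```r
library(aberrsim)

cfg  <- optical_config(na = 1.1, wavelength_um = 0.532,
                       grid_shape = c(64, 64, 64), sheet_fwhm_um = 2)
ipsf <- psf_from_pupil(cfg)

spec <- phantom_spec(grid_shape = c(64, 64, 64),
                     counts = c(dots = 10, lines = 5, circles = 3,
                                spheres = 3, shells = 3),
                     rng_seed = 1)
gt <- blur_with_psf(generate_phantom(spec), ipsf)

profile <- simulation_bounds(mode = "fixed_rms", amplitude = 2)
coeffs  <- sample_coefficients(profile, rng_seed = 2)
zernike_rms(coeffs)
#> [1] 2

apsf      <- psf_from_pupil(cfg, coeffs)
aberrated <- degrade(gt, motf = modified_otf(ipsf, apsf))
noisy     <- add_poisson_noise(aberrated, target_snr = 16, rng_seed = 3)
snr_estimate(noisy)
#> [1] 16.10447

unlist(metric_report(aberrated, gt))
#>     ssim  psnr_db     rmsc      snr dcts_mid
#>   0.8487  28.4708   1.7240   0.2688   0.00045

m <- train_reference_model(list(list(gt = gt, aberrated = aberrated)),
                           epochs = 2, patch_shape = c(64, 64, 64),
                           rng_seed = 4)
restored <- apply_tiled(m, aberrated, tile_shape = c(64, 64, 64),
                        overlap = 16)
unlist(metric_report(restored, gt))
#>     ssim  psnr_db     rmsc      snr dcts_mid
#>   0.8616  30.4789   2.0601   0.3169   0.00057
```

The aberration costs ~6 dB of PSNR and flattens contrast (RMSC 1.72 vs
the ground truth's 2.00); the learned linear filter recovers two of those
dB and most of the contrast on its training distribution. Deep models
plug into the same `predict()`/`apply_tiled()` contract.

Orientation analysis works the same way on any fibrous volume:
`segment_fibers()` (six-level Otsu) → `estimate_orientation()` (windowed
weighted vector summation) → `directional_variance()`.

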