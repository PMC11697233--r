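---
title: "Synthetic aberrations for 3D microscopy: model and methods"
author: "aberrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic aberrations for 3D microscopy: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fluorescence microscopy of thick samples suffers depth-dependent optical
aberrations: refractive-index inhomogeneities distort the wavefront at the
objective's back focal plane, degrading contrast and resolution the deeper
one images. Planes near the objective ("shallow" planes) are usually close
to diffraction-limited. This package implements the computational machinery
for a training-data strategy built on that observation: take
near-diffraction-limited volumes, degrade them with *known, synthetic*
aberrations drawn from a physically parameterized family, and use the
(ground truth, aberrated) pairs to train and evaluate restoration methods.
Everything needed for a desk-scale study is included: the wavefront and PSF
models, the degradation operator, a phantom generator, classical
deconvolution and preprocessing baselines, image-quality metrics, a tiled
prediction harness, and a 3D vessel-orientation analysis.

## Wavefront model

The aberrated wavefront at the pupil is expanded in Zernike polynomials,

$$\phi(r,\theta) = \sum_{m=0}^{M} c_m\,\phi_m(r,\theta),$$

with ANSI single-index ordering, $j = (n(n+2)+m)/2$. We use the
*orthonormal* (unit-RMS) normalization of the basis: each mode's
mean-square over the unit disk is one. This choice is what makes the
coefficient-space norm

$$\mathrm{RMS}_c = \sqrt{\sum_{m=3}^{M} c_m^2}$$

equal the true RMS wavefront distortion in radians; piston and the two
tilts (indices 0–2) displace the image without blurring it and are
excluded everywhere. Coefficients are in radians of phase at the emission
wavelength.

Random aberrations are sampled under per-mode bounds $|c_m| \le T_m$, each
coefficient independent and uniform on $[-T_m, T_m]$ (the distribution is a
design choice; only boundedness is physically prescribed). The default
simulation profile bounds the modes most prominent in real samples —
astigmatism (3, 5), defocus (4), and primary spherical (12) — at 1.5 rad
and all other modes up to radial order 4 ($M = 14$) at 0.5 rad. Two
normalizations turn a draw into a calibrated aberration:

* **upper-bounded** — multiply by $\Omega / \mathrm{RMS}_T$, where
  $\mathrm{RMS}_T$ is the norm of the bound vector, so $\Omega$ is a
  *maximum* RMS;
* **fixed-RMS** — multiply by $\Upsilon / \mathrm{RMS}_c$, so every draw
  has exactly RMS $\Upsilon$ (2 rad is the benchmark amplitude used
  throughout the tests).

Single named modes (defocus, astigmatism, coma, trefoil, spherical) place
the full amplitude on one mode or split it across a conjugate pair by a
caller-supplied angle, keeping the joint RMS at the requested amplitude.

## Forward optical model

PSFs are synthesized by scalar Fourier optics. On a lateral frequency grid
matched to the voxel size, the pupil is the disk $\rho \le NA/\lambda$;
defocus is propagated plane by plane with the angular-spectrum phase
$k z \sqrt{n^2 - NA^2 r^2}$, and the intensity PSF of plane $z$ is the
squared modulus of the inverse transform of the phase-laden pupil. For
light-sheet detection the intensity is additionally multiplied by a
Gaussian axial envelope whose FWHM is the nominal sheet thickness (2 µm by
default, the instrument we parameterize: 1.1 NA water dipping detection,
0.532 µm emission, 0.13 µm isotropic voxels); "thickness" is not otherwise
defined, and Gaussian-FWHM is the interpretation we adopt. Configurations
whose pupil would exceed the lateral Nyquist frequency are rejected.

Degradation follows the modified-OTF construction: with ideal PSF $i$ and
aberrated PSF $a$ (both unit-sum),

$$\mathrm{mOTF}(k) = \frac{\mathcal{F}a}{\mathcal{F}i}(k),$$

applied multiplicatively to the Fourier transform of the ground-truth
volume, then inverse transformed. Numerical choices:

* the ratio is only evaluated where $|\mathcal{F}i|$ exceeds $10^{-3}$ of
  its DC value and is zero outside — the unregularized ratio diverges at
  the OTF support edge; the DC term is exactly 1, so mean intensity is
  preserved;
* the inverse transform's imaginary residue (at machine-precision level)
  is discarded and negatives are clipped to zero, since Poisson noise
  needs non-negative rates;
* because out-of-support frequencies are zeroed, "zero aberration is the
  identity" holds to $10^{-5}$ for volumes whose spectrum lives inside the
  OTF support (e.g. anything blurred by the system PSF twice); a singly
  blurred volume retains $\sim\!10^{-4}$ relative energy at the support
  margin.

Noise is Poisson with an SNR convention tied to photon statistics:
$\mathrm{SNR} = \sqrt{S}$, where $S$ is the mean of voxels brighter than
1% of the maximum. The volume is rescaled so $S = \mathrm{SNR}^2$ photons
and one Poisson draw is taken per voxel. SNR 16 (256 photons) is the
benchmark level.

## Phantom generator

Test volumes contain five structure types — dots, lines (finite cylinders),
circles (rings/tori), spheres, and spherical shells — placed at uniformly
random positions and orientations in a 256³ grid of 0.13 µm voxels (tests
use smaller grids with proportionally chosen counts). Concrete readings of
the type names: lines are cylinders of finite length; circles are tori;
shells are spherical annuli. Rasterization is anti-aliased by 2×
supersampling per axis (8 subvoxel tests per voxel) inside each object's
bounding box; objects combine by voxelwise maximum, and each carries a
uniform intensity drawn from [0.5, 1].

Sizes default to structures *resolvable at the simulated NA* —
dot radii 0.26–0.5 µm, cylinder radii 0.26–0.5 µm, ring and sphere radii
up to ~2 µm — emulating vesicles, fibers and membranes as they appear in
cellular imaging. Keeping the structures above the diffraction limit also
keeps the diffraction-limited reference structurally faithful to the
phantom, which is the regime a de-aberration method targets; the generator
exposes all ranges for studies of other regimes. What the phantoms do
*not* emulate: spatially varying background, autofluorescence, scattering,
or tissue-scale texture — conclusions from phantom tests transfer to real
data only insofar as degradation is the dominant effect.

## Training corpora

A corpus is built by degrading each source volume with $n$ independently
sampled aberrations (the standard session: 50 phantoms × 10 aberrations =
500 pairs). Every pair records its sampling seed, coefficients, RMS, and
SNR target in a manifest, so any aberrated volume is bit-reproducible from
(source, seed, configuration) alone. Shallow-subvolume extraction is a
plain z-crop with a half-open, 0-based window (fractions floored to whole
planes); the choice of how shallow is "shallow enough" is left to the
user, with ~20% resolution degradation a reasonable working cutoff.
Patch extraction (default 64³) supports strided grids (the final origin is
snapped so the grid covers the volume) and seeded random sampling, with
coordinates kept for exact reassembly.

## Restoration baselines and preprocessing

Richardson–Lucy deconvolution uses the standard multiplicative updates
with circular FFT convolution and the space-flipped-PSF adjoint,
initialized with the observed image; 20 iterations is the protocol
default. A property worth knowing when interpreting benchmarks against a
*blurred* reference: RL with the matched aberrated PSF converges toward
the unblurred scene, so its similarity to a diffraction-limited reference
peaks early (typically 5–10 iterations here) and can fall below the raw
input's similarity by iteration 20 as the estimate out-resolves the
reference. The relative ordering "matched aberrated PSF beats ideal PSF"
is robust; "20-iteration RL beats raw" is not, in these phantom
conditions.

Preprocessing: uniform background subtraction (clipped at zero); depth
attenuation compensation $I(z) = I_0(z)\,e^{\alpha z}$ with $\alpha$ per
*plane* (the depth unit is the plane index from the shallow side; default
$\alpha = 0.01$); and time-lapse renormalization for restoration models
that normalize each time point independently — ratios
$r_k = \overline{\mathrm{raw}}_{k,\mathrm{pre}} /
\overline{\mathrm{raw}}_{k,\mathrm{post}}$ rescale prediction $k$ by
$r_k/r_1$. Means are taken over whole volumes.

## Image-quality metrics

* **SSIM / PSNR** — full-volume 3D SSIM with a Gaussian window
  (σ = 1.5, radius 5) and stability constants $K_1 = 0.01$, $K_2 = 0.03$;
  the dynamic range is the reference's max − min. PSNR is
  $10\log_{10}(L^2/\mathrm{MSE})$ in dB. The implementation agrees with
  scikit-image's Gaussian-weighted SSIM to ~0.01 on shared inputs.
* **RMS contrast** — divide by the mean, bin 3× (block average, remainders
  cropped), sample standard deviation; scale-invariant by construction.
* **Photon SNR** — $\sqrt{S}$ with the 1%-of-max threshold above.
* **DCTS sharpness** — Shannon entropy of the L2-normalized 2D DCT-II
  power restricted to the optical support radius, divided by the number of
  supported coefficients; an all-zero plane is defined as 0. The exact
  normalization constant varies across the autofocus literature; ours is
  fixed as stated and suited to relative comparisons only.

## Tiled prediction harness

The restoration-model contract is minimal: `predict(model, volume)`
returns an equally shaped array, deterministically. Large volumes are
processed in overlapping tiles (default overlap 32 voxels) recombined with
separable linear ramps; accumulated weights are divided out, so blend
weights sum to exactly one and an identity model is reproduced to within
$10^{-6}$ for any tiling.

The shipped reference model is a *learned linear restoration operator*: a
per-frequency filter $H = \sum G\bar A / (\sum |A|^2 + \lambda)$ fitted to
(aberrated, ground-truth) patch spectra by ridge-regularized least squares
over seeded training passes, then windowed to a compact real-space
convolution kernel (default 15³) so it applies to any volume shape. It is
deliberately small and linear — a floor for what a trained operator
achieves, deterministic and inspectable; deep architectures plug in
through the same contract. Being linear and shared across aberrations, it
corrects the *average* degradation of its training distribution and cannot
undo individual phase structure the way a deep nonlinear model can.

## 3D orientation and directional variance

Fiber/vessel voxels are segmented by six-level Otsu thresholding (a
dynamic program over a 256-bin histogram maximizing between-class
variance); the lowest class is background. For each fiber voxel, all
deduplicated lattice directions through the center of an $n^3$ window
(n odd, ideally 2–3 fiber diameters) are scored with weight

$$w = \frac{\text{contiguous in-mask length through the center}}
          {1 + \mathrm{var}/\mathrm{mean}^2 \text{ of intensities along the line}},$$

our concrete reading of "weighted by length and intensity variations";
the weighted vector sum — each direction sign-aligned to the
highest-weight direction, since fiber orientation is axial — defines the
voxel orientation. On cylinders with Gaussian cross-sections the recovered
axis is within 1° for windows 2–3× the fiber width; on *binary* masks
whose width approaches the window size, many tilted chords tie at maximal
weight and accuracy degrades — intensity texture is what disambiguates.

Orientations are reported as four angles in degrees on [0, 180): azimuth
θ (xy-projection vs x), β (zx-projection vs x), γ (yz-projection vs −y),
and polar φ (from the depth axis), which satisfy
$\tan^2\varphi = 1/\tan^2\beta + 1/\tan^2\gamma$. Internally all
derivations use direction cosines; angles are computed only for
reporting, which sidesteps the tangent singularities at 0° and 90°.

Directional variance summarizes a region's orientation spread. Each of
the $k$ fiber voxels contributes the unit vector
$(f\cos 2\theta,\; f\sin 2\theta,\; SI)/\sqrt{1+f^2}$ with
$f = \sqrt{1/\tan^2 2\beta + 1/\tan^2 2\gamma}$ and
$SI = -\operatorname{sign}(\varphi - 90)$, and

$$\mathrm{DV} = 1 - \left\| \tfrac{1}{k}\textstyle\sum_j v_j \right\|.$$

Since each contribution has unit norm, DV provably lies in [0, 1]: 0 for
perfectly parallel fields, approaching 1 under isotropy (0.99 at
$k = 10^4$ random directions). At $\varphi = 90$ exactly the sign factor
is 0/0; we define $SI = 0$ there, which removes the z-contribution of
in-plane fibers — the one convention the formulas leave open.

## Problem sizes and determinism

The test suite and the reproduction script run everything at reduced desk
scale as the package's own study sizes: 64³ grids for benchmark volumes
(with structure counts scaled from the 256³ defaults), 32–48³ grids for
unit properties, 10 evaluation pairs for restoration orderings, 500 pairs
for corpus bookkeeping, $10^4$ directions for isotropy. Every stochastic
operation takes an explicit seed and is bit-reproducible given it; child
seeds for corpus pairs derive from one master seed and are recorded in
the manifest.

## Known limitations

Scalar, laterally invariant optics only (widefield and Gaussian-sheet
light-sheet detection); no vectorial high-NA polarization effects, no
confocal/two-photon/structured-illumination forward models, no spatially
varying aberration across the field. The reference restoration model is
linear; published deep architectures should be plugged in for serious
restoration studies. TIFF storage quantizes to 32-bit normalized samples
(relative error below $2^{-32}$, with the physical scale in a JSON
sidecar).
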