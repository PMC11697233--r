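# Scalar Fourier-optics forward model: pupil-function PSF synthesis for
# widefield / light-sheet detection, modified-OTF degradation, and
# SNR-controlled Poisson noise.
#
# Defocus is propagated with the angular-spectrum phase
# k z sqrt(n^2 - NA^2 r^2), k = 2 pi / lambda, per axial plane. The
# light-sheet "thickness" is modeled as the FWHM of a Gaussian axial
# illumination envelope multiplying the detection PSF intensity.

#' Optical configuration for PSF synthesis
#'
#' @param na detection numerical aperture (must be below `medium_index`).
#' @param wavelength_um emission wavelength in micrometers.
#' @param medium_index immersion refractive index (default 1.33, water).
#' @param voxel_um voxel size (dz, dy, dx) in micrometers.
#' @param grid_shape grid (nz, ny, nx) in voxels, each >= 8.
#' @param sheet_fwhm_um light-sheet axial FWHM in micrometers, or `NULL`
#'   for widefield detection.
#' @return an `optical_config` object.
#' @export
optical_config <- function(na = 1.1, wavelength_um = 0.532,
                           medium_index = 1.33,
                           voxel_um = c(0.13, 0.13, 0.13),
                           grid_shape = c(64, 64, 64),
                           sheet_fwhm_um = 2) {
  if (na <= 0 || na >= medium_index)
    stop("need 0 < na < medium_index")
  if (any(voxel_um <= 0)) stop("voxel sizes must be positive")
  if (any(grid_shape < 8)) stop("grid dimensions must be >= 8")
  if (!is.null(sheet_fwhm_um) && sheet_fwhm_um <= 0)
    stop("sheet_fwhm_um must be positive (or NULL for widefield)")
  cutoff <- na / wavelength_um              # pupil radius, cycles/um
  nyq <- 1 / (2 * max(voxel_um[2:3]))
  if (cutoff > nyq)
    stop(sprintf(paste0("pupil extends beyond lateral Nyquist ",
                        "(NA/lambda = %.3f > %.3f cycles/um); ",
                        "use finer lateral sampling"), cutoff, nyq))
  structure(list(na = na, wavelength_um = wavelength_um,
                 medium_index = medium_index,
                 voxel_um = as.numeric(voxel_um),
                 grid_shape = as.integer(grid_shape),
                 sheet_fwhm_um = sheet_fwhm_um),
            class = "optical_config")
}

#' Back-focal-plane pupil coordinate grids
#'
#' Lateral spatial frequencies are laid out in FFT-native order matched to
#' the configured grid; the pupil radius is normalized so r = 1 at the
#' cutoff NA/lambda.
#'
#' @param config an [optical_config()].
#' @return list with matrices `r` (normalized radius), `theta` (azimuth,
#'   (-pi, pi]) and logical `mask` (inside the pupil), each ny x nx.
#' @export
pupil_grid <- function(config) {
  stopifnot(inherits(config, "optical_config"))
  ny <- config$grid_shape[2]; nx <- config$grid_shape[3]
  ky <- fft_freq(ny, config$voxel_um[2])
  kx <- fft_freq(nx, config$voxel_um[3])
  KY <- matrix(ky, ny, nx)
  KX <- matrix(kx, ny, nx, byrow = TRUE)
  rho <- sqrt(KX^2 + KY^2)
  r <- rho / (config$na / config$wavelength_um)
  theta <- atan2(KY, KX)
  list(r = r, theta = theta, mask = r <= 1)
}

#' Synthesize a 3D PSF from the pupil function
#'
#' For each axial plane z, the amplitude PSF is the inverse 2D Fourier
#' transform of the pupil disk carrying the Zernike aberration phase plus
#' the angular-spectrum defocus phase; intensity is its squared modulus.
#' With a light-sheet configured, intensity is further multiplied by a
#' Gaussian axial envelope of the configured FWHM centered at focus.
#' The result is origin-centered and normalized to unit sum.
#'
#' @param config an [optical_config()].
#' @param coeffs Zernike coefficient vector (radians, ANSI order), or
#'   `NULL` / all zeros for the ideal (unaberrated) PSF.
#' @return a [volume3d()] PSF, non-negative, summing to 1, peak at the
#'   center voxel when unaberrated.
#' @export
psf_from_pupil <- function(config, coeffs = NULL) {
  stopifnot(inherits(config, "optical_config"))
  g <- pupil_grid(config)
  nz <- config$grid_shape[1]; ny <- config$grid_shape[2]
  nx <- config$grid_shape[3]
  mask <- g$mask
  rc <- pmin(g$r, 1)                       # clamp for mode evaluation
  phase_ab <- if (is.null(coeffs) || all(coeffs == 0)) {
    matrix(0, ny, nx)
  } else {
    ph <- wavefront(coeffs, rc, g$theta)
    ph[!mask] <- 0
    ph
  }
  k0 <- 2 * pi / config$wavelength_um
  # axial wavenumber on the pupil: k sqrt(n^2 - NA^2 r^2); real inside pupil
  kz <- k0 * sqrt(pmax(config$medium_index^2 - (config$na * rc)^2, 0))
  kz[!mask] <- 0
  zs <- (seq_len(nz) - (floor(nz / 2) + 1)) * config$voxel_um[1]
  psf <- array(0, c(nz, ny, nx))
  pupil0 <- mask * exp(1i * phase_ab)
  for (iz in seq_len(nz)) {
    p <- pupil0 * exp(1i * kz * zs[iz])
    amp <- stats::fft(p, inverse = TRUE)
    psf[iz, , ] <- fftshift2(Mod(amp)^2)
  }
  if (!is.null(config$sheet_fwhm_um)) {
    env <- exp(-4 * log(2) * zs^2 / config$sheet_fwhm_um^2)
    psf <- psf * env                       # recycles along z (dim 1)
  }
  volume3d(psf / sum(psf), voxel_um = config$voxel_um)
}

#' Modified optical transfer function (ratio of aberrated to ideal OTF)
#'
#' mOTF(k) = FT(aPSF)(k) / FT(iPSF)(k) wherever the ideal OTF magnitude
#' exceeds `eps` times its DC value, and 0 outside that support; the DC
#' term is exactly 1 since both PSFs sum to 1. Returned in FFT-native
#' layout, ready to multiply an image spectrum.
#'
#' @param ipsf ideal PSF ([volume3d()], origin-centered, unit sum).
#' @param apsf aberrated PSF, same shape.
#' @param eps relative support threshold on the ideal OTF (default 1e-3);
#'   the unregularized ratio diverges at the OTF edge.
#' @return complex 3D array (FFT-native layout).
#' @export
modified_otf <- function(ipsf, apsf, eps = 1e-3) {
  ia <- vol_data(ipsf); aa <- vol_data(apsf)
  if (!identical(dim(ia), dim(aa))) stop("PSF shapes differ")
  oi <- fftn(ifftshift3(ia))
  oa <- fftn(ifftshift3(aa))
  support <- Mod(oi) > eps * Mod(oi[1, 1, 1])
  m <- array(0 + 0i, dim(ia))
  m[support] <- oa[support] / oi[support]
  m[1, 1, 1] <- 1 + 0i
  m
}

#' Degrade a ground-truth volume through the modified OTF
#'
#' Fourier transforms the volume, multiplies by the mOTF built from the
#' ideal and aberrated PSFs of `config`/`coeffs`, inverse transforms,
#' discards the (numerically negligible) imaginary residue and clips
#' negatives to zero. Noise is applied separately by
#' [add_poisson_noise()]. Mean intensity is preserved (the DC ratio is 1)
#' up to clipping.
#'
#' @param gt ground-truth [volume3d()] matching the config grid.
#' @param config an [optical_config()] (ignored when `motf` is given).
#' @param coeffs Zernike coefficients of the aberration (ignored when
#'   `motf` is given).
#' @param motf optional precomputed [modified_otf()] for reuse across
#'   volumes.
#' @return degraded [volume3d()].
#' @export
degrade <- function(gt, config = NULL, coeffs = NULL, motf = NULL) {
  a <- vol_data(gt)
  if (is.null(motf)) {
    if (is.null(config) || is.null(coeffs))
      stop("need either motf or both config and coeffs")
    if (!identical(dim(a), as.integer(config$grid_shape)) &&
        !identical(dim(a), config$grid_shape))
      stop("volume shape does not match config grid")
    motf <- modified_otf(psf_from_pupil(config, NULL),
                         psf_from_pupil(config, coeffs))
  }
  if (!identical(dim(a), dim(motf))) stop("volume/mOTF shape mismatch")
  out <- ifftn(fftn(a) * motf)
  out <- pmax(Re(out), 0)
  dim(out) <- dim(a)
  volume3d(out, voxel_um = vol_voxel(gt))
}

#' Add SNR-controlled Poisson noise
#'
#' The photon SNR is defined as sqrt(S) where S is the mean of all voxels
#' brighter than `threshold_frac` of the maximum of the noise-free volume.
#' The volume is rescaled so that S equals `target_snr`^2 photons, then an
#' independent Poisson draw is taken per voxel.
#'
#' @param volume non-negative [volume3d()], not identically zero.
#' @param target_snr desired SNR (e.g. 16 gives a 256-photon signal mean).
#' @param threshold_frac signal threshold as a fraction of the maximum
#'   (default 0.01).
#' @param rng_seed optional integer seed; deterministic given it.
#' @return noisy [volume3d()] in photon units.
#' @export
add_poisson_noise <- function(volume, target_snr, threshold_frac = 0.01,
                              rng_seed = NULL) {
  a <- vol_data(volume)
  if (any(a < 0)) stop("volume must be non-negative")
  mx <- max(a)
  if (mx <= 0) stop("volume is identically zero; SNR undefined")
  if (target_snr <= 0) stop("target_snr must be positive")
  sig <- mean(a[a > threshold_frac * mx])
  scaled <- a * (target_snr^2 / sig)
  noisy <- as.numeric(with_seed(rng_seed, stats::rpois(length(scaled), scaled)))
  dim(noisy) <- dim(a)
  volume3d(noisy, voxel_um = vol_voxel(volume))
}
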