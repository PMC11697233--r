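# Volumetric image-quality metrics: SSIM, PSNR, RMS contrast, photon SNR,
# and DCT Shannon entropy sharpness (DCTS).

# separable Gaussian filtering with symmetric (reflect) boundary handling
gauss_kernel <- function(sigma, radius = ceiling(3.5 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# filter a 3D array along one axis with symmetric padding
filter_axis <- function(a, k, axis) {
  r <- (length(k) - 1L) / 2L
  d <- dim(a)
  n <- d[axis]
  # reflected index vector for symmetric padding
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1 - rev(seq_len(min(r, n))))
  if (r > n) stop("kernel radius exceeds axis length")
  perm <- c(axis, setdiff(1:3, axis))
  b <- aperm(a, perm)
  db <- dim(b)
  bp <- b[idx, , , drop = FALSE]
  out <- array(0, db)
  for (j in seq_along(k)) {
    out <- out + k[j] * bp[j:(j + n - 1L), , , drop = FALSE]
  }
  aperm(out, order(perm))
}

gauss_filter3 <- function(a, sigma = 1.5) {
  k <- gauss_kernel(sigma)
  filter_axis(filter_axis(filter_axis(a, k, 1), k, 2), k, 3)
}

#' Volumetric SSIM and PSNR against a reference
#'
#' Full-volume 3D structural similarity (Gaussian window, sigma 1.5,
#' stability constants K1 = 0.01, K2 = 0.03) and peak signal-to-noise
#' ratio in dB. The dynamic range is taken from the reference
#' (max - min).
#'
#' @param test restored or degraded [volume3d()].
#' @param reference ground-truth [volume3d()] of identical shape.
#' @return list with `ssim` (mean SSIM map value) and `psnr_db`.
#' @export
ssim_psnr <- function(test, reference) {
  x <- vol_data(test); y <- vol_data(reference)
  if (!identical(dim(x), dim(y))) stop("test/reference shape mismatch")
  L <- max(y) - min(y)
  if (L <= 0) stop("reference has zero dynamic range")
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  mx <- gauss_filter3(x); my <- gauss_filter3(y)
  sxx <- gauss_filter3(x * x) - mx * mx
  syy <- gauss_filter3(y * y) - my * my
  sxy <- gauss_filter3(x * y) - mx * my
  ssim_map <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mse <- mean((x - y)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(L^2 / mse)
  list(ssim = mean(ssim_map), psnr_db = psnr)
}

# block-average binning by an integer factor (trailing remainder cropped)
bin_volume <- function(a, f) {
  if (f == 1) return(a)
  d <- dim(a)
  dn <- d %/% f
  if (any(dn < 1)) stop("bin factor too large for volume")
  a <- a[seq_len(dn[1] * f), seq_len(dn[2] * f), seq_len(dn[3] * f),
         drop = FALSE]
  dim(a) <- c(f, dn[1], f, dn[2], f, dn[3])
  out <- apply(a, c(2, 4, 6), mean)
  out
}

#' RMS contrast of a mean-normalized, binned volume
#'
#' The volume is divided by its mean intensity, block-averaged by
#' `bin_factor` to suppress noise, and the sample standard deviation of
#' the binned values is returned. Invariant to overall intensity scaling.
#'
#' @param volume a [volume3d()] with positive mean.
#' @param bin_factor integer binning factor (default 3).
#' @return non-negative RMS contrast.
#' @export
rms_contrast <- function(volume, bin_factor = 3) {
  a <- vol_data(volume)
  m <- mean(a)
  if (m <= 0) stop("volume mean must be positive")
  b <- bin_volume(a / m, as.integer(bin_factor))
  stats::sd(b)
}

#' Photon SNR estimate
#'
#' sqrt(S) where S is the mean of all voxels brighter than
#' `threshold_frac` of the volume maximum; the same definition used when
#' injecting Poisson noise, so a noise-free volume scaled for SNR 16 has
#' an above-threshold mean of 256.
#'
#' @param volume non-negative [volume3d()].
#' @param threshold_frac signal threshold fraction (default 0.01).
#' @return non-negative SNR.
#' @export
snr_estimate <- function(volume, threshold_frac = 0.01) {
  a <- vol_data(volume)
  if (any(a < 0)) stop("volume must be non-negative")
  sel <- a > threshold_frac * max(a)
  if (!any(sel)) stop("no voxel above the signal threshold")
  sqrt(mean(a[sel]))
}

# 1D DCT-II along columns via the even-reorder FFT identity
dct2_matrix <- function(x) {
  dct_axis <- function(m) {
    n <- nrow(m)
    v <- m[c(seq(1, n, 2), rev(seq(2, n, 2))), , drop = FALSE]
    f <- stats::mvfft(v)
    w <- exp(-1i * pi * (0:(n - 1)) / (2 * n))
    2 * Re(w * f)
  }
  t(dct_axis(t(dct_axis(x))))
}

#' DCT Shannon entropy sharpness (DCTS) of a 2D plane
#'
#' Shannon entropy of the L2-normalized DCT-II power restricted to the
#' optical support radius, divided by the number of supported
#' coefficients. Sharp images concentrate energy in few coefficients
#' (low entropy normalized per coefficient rises with genuine high-
#' frequency content, falls under blur). An all-zero plane returns 0.
#'
#' @param plane 2D numeric matrix.
#' @param otf_radius_frac support radius as a fraction of the full DCT
#'   frequency extent (default 1, whole plane).
#' @return non-negative sharpness value.
#' @export
dcts <- function(plane, otf_radius_frac = 1) {
  if (is.null(dim(plane)) || length(dim(plane)) != 2)
    stop("plane must be a 2D matrix")
  if (all(plane == 0)) return(0)
  d <- dct2_matrix(plane)
  nr <- nrow(d); nc <- ncol(d)
  u <- matrix((0:(nr - 1)) / nr, nr, nc)
  v <- matrix((0:(nc - 1)) / nc, nr, nc, byrow = TRUE)
  sel <- sqrt(u^2 + v^2) <= otf_radius_frac
  c2 <- d[sel]^2
  tot <- sum(c2)
  if (tot == 0) return(0)
  p <- c2 / tot
  p <- p[p > 0]
  -sum(p * log(p)) / sum(sel)
}

#' Metric report for a test/reference volume pair
#'
#' Convenience wrapper computing all package metrics at their defaults.
#'
#' @param test,reference matching [volume3d()]s.
#' @return one-row data.frame with ssim, psnr_db, rmsc, snr and mid-plane
#'   dcts of the test volume.
#' @export
metric_report <- function(test, reference) {
  sp <- ssim_psnr(test, reference)
  a <- vol_data(test)
  mid <- a[floor(dim(a)[1] / 2) + 1, , ]
  data.frame(ssim = sp$ssim, psnr_db = sp$psnr_db,
             rmsc = rms_contrast(test),
             snr = snr_estimate(test),
             dcts_mid = dcts(mid))
}
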