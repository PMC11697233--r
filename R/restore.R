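# Classical restoration baseline (Richardson-Lucy) and preprocessing:
# background subtraction, depth attenuation compensation, and time-lapse
# intensity renormalization.

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative updates for Poisson-noise imaging with a known
#' PSF, using circular FFT convolution and the flipped-PSF adjoint.
#' Iterates stay non-negative; total intensity is approximately conserved.
#'
#' @param observed non-negative [volume3d()].
#' @param psf origin-centered PSF; normalized to unit sum with a warning
#'   if it is not already.
#' @param iterations number of RL updates (default 20).
#' @return restored [volume3d()].
#' @export
richardson_lucy <- function(observed, psf, iterations = 20) {
  a <- vol_data(observed)
  if (any(a < 0)) stop("observed volume must be non-negative")
  k <- vol_data(psf)
  s <- sum(k)
  if (abs(s - 1) > 1e-6) {
    warning("PSF does not sum to 1; normalizing")
    k <- k / s
  }
  k <- pad_center(k, dim(a))
  otf <- fftn(ifftshift3(k))
  cotf <- Conj(otf)              # FT of the space-flipped (adjoint) PSF
  conv <- function(x, o) {
    r <- Re(ifftn(fftn(x) * o)); dim(r) <- dim(a); r
  }
  eps <- 1e-12 * max(a)
  est <- a
  est[est <= 0] <- eps
  for (it in seq_len(iterations)) {
    blurred <- pmax(conv(est, otf), eps)
    est <- est * conv(a / blurred, cotf)
    est <- pmax(est, 0)
  }
  volume3d(est, voxel_um = vol_voxel(observed))
}

#' Depth attenuation compensation
#'
#' Multiplies plane z (counted from the shallow side, z = 0 for the first
#' plane) by exp(alpha * z), reversing the exponential intensity falloff
#' with imaging depth. alpha is per plane; the default 0.01 suits typical
#' cleared-tissue and worm stacks.
#'
#' @param volume a [volume3d()].
#' @param alpha attenuation factor per plane (default 0.01).
#' @param depth_axis array dimension holding depth (default 1, the z axis).
#' @return corrected [volume3d()].
#' @export
attenuation_correct <- function(volume, alpha = 0.01, depth_axis = 1) {
  a <- vol_data(volume)
  nzp <- dim(a)[depth_axis]
  fac <- exp(alpha * (seq_len(nzp) - 1))
  perm <- c(depth_axis, setdiff(1:3, depth_axis))
  b <- aperm(a, perm)
  b <- b * fac                       # recycles along the (now first) depth axis
  out <- aperm(b, order(perm))
  volume3d(out, voxel_um = vol_voxel(volume))
}

#' Uniform background subtraction
#'
#' Subtracts a constant camera/background level and clips at zero.
#'
#' @param volume a [volume3d()].
#' @param background_level non-negative constant (e.g. the mean of dark
#'   frames).
#' @return background-subtracted [volume3d()].
#' @export
subtract_background <- function(volume, background_level) {
  if (background_level < 0) stop("background_level must be >= 0")
  a <- pmax(vol_data(volume) - background_level, 0)
  volume3d(a, voxel_um = vol_voxel(volume))
}

#' Time-lapse intensity renormalization
#'
#' Restoration networks that normalize each time point independently
#' introduce artificial intensity fluctuations in time-lapse data. This
#' computes per-time normalization ratios r_k = mean(raw before
#' normalization) / mean(raw after normalization) and rescales prediction
#' k by r_k / r_1, pinning everything to the first time point.
#'
#' @param raw_pre list of raw volumes before normalization, time-ordered.
#' @param raw_post matching list after normalization.
#' @param predictions matching list of predicted volumes.
#' @return list of rescaled prediction volumes; attribute `"ratios"` holds
#'   the r_k.
#' @export
timelapse_renormalize <- function(raw_pre, raw_post, predictions) {
  K <- length(predictions)
  if (length(raw_pre) != K || length(raw_post) != K)
    stop("raw_pre, raw_post and predictions must have equal length")
  if (K < 1) stop("need at least one time point")
  r <- vapply(seq_len(K), function(k) {
    m_pre <- mean(vol_data(raw_pre[[k]]))
    m_post <- mean(vol_data(raw_post[[k]]))
    if (m_pre <= 0 || m_post <= 0)
      stop("zero-mean volume at time point ", k)
    m_pre / m_post
  }, numeric(1))
  out <- lapply(seq_len(K), function(k) {
    p <- predictions[[k]]
    volume3d(vol_data(p) * (r[k] / r[1]), voxel_um = vol_voxel(p))
  })
  attr(out, "ratios") <- r
  out
}
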