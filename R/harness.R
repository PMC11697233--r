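# Pluggable restoration-model contract plus tiled volume application with
# seam-free linear blending.
#
# The model contract is simply: predict(model, volume_array) returns an
# array of identical shape, deterministically. The reference model shipped
# here is a learned linear restoration operator: a per-frequency filter
# estimated from (aberrated, ground-truth) pairs by regularized
# least squares, compacted to a small real-space convolution kernel so it
# applies to volumes of any shape. The contract accepts any user model
# (e.g. a wrapper around an external deep network).

#' Train the reference restoration model on (aberrated, ground truth) pairs
#'
#' Fits the linear filter H(k) minimizing the mean squared error between
#' filtered aberrated patches and their ground truths, i.e.
#' H = sum(G conj(A)) / (sum |A|^2 + lambda) per frequency, accumulated
#' over `epochs` passes of randomly drawn training patches. The filter is
#' then windowed to a compact real-space kernel of side `kernel_size` so
#' prediction works on arbitrary volume shapes. The per-epoch training
#' loss (MSE over a fixed evaluation subset) is logged on the returned
#' object.
#'
#' @param pairs a `training_manifest` from [make_training_pairs()], or a
#'   list of `list(gt = , aberrated = )` volume pairs.
#' @param epochs passes of patch sampling (default 2).
#' @param patch_shape training patch shape (clipped to the volume size).
#' @param patches_per_epoch random patches drawn per pair per epoch.
#' @param kernel_size side of the compact real-space kernel (odd).
#' @param lambda relative ridge regularizer on the spectral fit.
#' @param rng_seed seed controlling patch sampling; training is
#'   deterministic given it.
#' @return a `restoration_model` with elements `kernel`, `loss` (per
#'   epoch), and training metadata.
#' @export
train_reference_model <- function(pairs, epochs = 2,
                                  patch_shape = c(64, 64, 64),
                                  patches_per_epoch = 4,
                                  kernel_size = 15, lambda = 1e-3,
                                  rng_seed = NULL) {
  plist <- manifest_pairs(pairs)
  if (length(plist) < 1) stop("no training pairs")
  if (kernel_size %% 2 != 1) stop("kernel_size must be odd")
  d0 <- dim(vol_data(plist[[1]]$gt))
  p <- pmin(rep(as.integer(patch_shape), length.out = 3), d0)
  seeds <- derive_seeds(if (is.null(rng_seed)) 1L else rng_seed,
                        epochs * length(plist))
  num <- array(0 + 0i, p)
  den <- array(0, p)
  loss <- numeric(epochs)
  si <- 0L
  for (ep in seq_len(epochs)) {
    for (pi in seq_along(plist)) {
      si <- si + 1L
      gt <- vol_data(plist[[pi]]$gt)
      ab <- vol_data(plist[[pi]]$aberrated)
      pk <- patchify(ab, p, count = patches_per_epoch, rng_seed = seeds[si])
      for (j in seq_len(nrow(pk$coords))) {
        o <- pk$coords[j, ]
        gpatch <- gt[o[1]:(o[1] + p[1] - 1L), o[2]:(o[2] + p[2] - 1L),
                     o[3]:(o[3] + p[3] - 1L)]
        A <- fftn(pk$patches[[j]])
        G <- fftn(gpatch)
        num <- num + G * Conj(A)
        den <- den + Mod(A)^2
      }
    }
    H <- num / (den + lambda * mean(den))
    kern <- compact_kernel(H, kernel_size)
    loss[ep] <- mean(vapply(plist, function(pr) {
      pred <- conv_kernel(vol_data(pr$aberrated), kern)
      mean((pred - vol_data(pr$gt))^2)
    }, numeric(1)))
  }
  structure(list(kernel = kern, loss = loss, patch_shape = p,
                 kernel_size = kernel_size, lambda = lambda,
                 n_pairs = length(plist), epochs = epochs,
                 rng_seed = rng_seed),
            class = "restoration_model")
}

# normalize a manifest or plain list to list(list(gt=, aberrated=), ...)
manifest_pairs <- function(pairs) {
  if (inherits(pairs, "training_manifest")) {
    vols <- attr(pairs, "volumes")
    if (!is.null(vols)) return(vols)
    lapply(seq_len(nrow(pairs)), function(i)
      list(gt = read_volume(pairs$gt_path[i]),
           aberrated = read_volume(pairs$aberrated_path[i])))
  } else pairs
}

# window the spectral filter to a compact centered real-space kernel
compact_kernel <- function(H, kernel_size) {
  k <- fftshift3(Re(ifftn(H)))
  d <- dim(k)
  ctr <- floor(d / 2) + 1L
  r <- (kernel_size - 1L) / 2L
  r <- pmin(r, ctr - 1L, d - ctr)
  kc <- k[(ctr[1] - r[1]):(ctr[1] + r[1]),
          (ctr[2] - r[2]):(ctr[2] + r[2]),
          (ctr[3] - r[3]):(ctr[3] + r[3]), drop = FALSE]
  # preserve the DC response of the full filter
  dc <- Re(H[1, 1, 1])
  if (abs(sum(kc)) > 1e-12) kc <- kc * (dc / sum(kc))
  kc
}

# circular convolution of a volume with a small centered kernel
conv_kernel <- function(a, kern) {
  k <- pad_center(kern, dim(a))
  out <- Re(ifftn(fftn(a) * fftn(ifftshift3(k))))
  dim(out) <- dim(a)
  out
}

#' @export
print.restoration_model <- function(x, ...) {
  cat(sprintf(paste0("restoration_model: learned linear filter, kernel %s,",
                     " trained on %d pair(s), %d epoch(s)\n"),
              paste(dim(x$kernel), collapse = "x"), x$n_pairs, x$epochs))
  cat("  final training loss:", x$loss[length(x$loss)], "\n")
  invisible(x)
}

#' Apply a restoration model to a volume (or tile)
#' @param object a `restoration_model`.
#' @param volume 3D array or [volume3d()].
#' @param ... unused.
#' @return restored array of identical shape, clipped at zero.
#' @export
predict.restoration_model <- function(object, volume, ...) {
  a <- vol_data(volume)
  pmax(conv_kernel(a, object$kernel), 0)
}

# 1D blending profile: linear ramps over the overlap at interior edges,
# flat (weight 1) at volume borders. Opposing ramps of two neighboring
# tiles sum to exactly 1.
ramp_profile <- function(len, overlap, first, last) {
  w <- rep(1, len)
  if (!first && overlap > 0) {
    n <- min(overlap, len)
    w[seq_len(n)] <- (seq_len(n) - 0.5) / overlap
  }
  if (!last && overlap > 0) {
    n <- min(overlap, len)
    w[len - seq_len(n) + 1L] <- (seq_len(n) - 0.5) / overlap
  }
  w
}

# tile origins covering an axis with the requested overlap
tile_origins <- function(n, tile, overlap) {
  if (tile >= n) return(1L)
  step <- tile - overlap
  if (step < 1) stop("overlap must be smaller than the tile")
  o <- seq(1L, n - tile + 1L, by = step)
  if (o[length(o)] != n - tile + 1L) o <- c(o, n - tile + 1L)
  as.integer(o)
}

#' Apply a model over a large volume in overlapping tiles
#'
#' Splits the volume into overlapping tiles, applies the model to each,
#' and recombines with linear ramp weights; accumulated weights are
#' divided out so the blend weights sum to exactly 1 at every voxel and
#' an identity model reproduces its input.
#'
#' @param model anything with a `predict(model, tile)` method returning an
#'   array of the tile's shape (e.g. a `restoration_model`).
#' @param volume input [volume3d()] or 3D array.
#' @param tile_shape tile size per axis (default 256^3, clipped to the
#'   volume).
#' @param overlap voxels of overlap between neighboring tiles
#'   (default 32).
#' @return restored volume (same class as input where possible).
#' @export
apply_tiled <- function(model, volume, tile_shape = c(256, 256, 256),
                        overlap = 32) {
  a <- vol_data(volume)
  d <- dim(a)
  tl <- pmin(rep(as.integer(tile_shape), length.out = 3), d)
  ov <- rep(as.integer(overlap), length.out = 3)
  ov <- pmin(ov, tl - 1L)
  oz <- tile_origins(d[1], tl[1], ov[1])
  oy <- tile_origins(d[2], tl[2], ov[2])
  ox <- tile_origins(d[3], tl[3], ov[3])
  acc <- array(0, d); wts <- array(0, d)
  for (z0 in oz) for (y0 in oy) for (x0 in ox) {
    iz <- z0:(z0 + tl[1] - 1L); iy <- y0:(y0 + tl[2] - 1L)
    ix <- x0:(x0 + tl[3] - 1L)
    pred <- predict(model, a[iz, iy, ix, drop = FALSE])
    wz <- ramp_profile(tl[1], ov[1], z0 == oz[1], z0 == oz[length(oz)])
    wy <- ramp_profile(tl[2], ov[2], y0 == oy[1], y0 == oy[length(oy)])
    wx <- ramp_profile(tl[3], ov[3], x0 == ox[1], x0 == ox[length(ox)])
    w <- outer(outer(wz, wy), wx)
    acc[iz, iy, ix] <- acc[iz, iy, ix] + w * pred
    wts[iz, iy, ix] <- wts[iz, iy, ix] + w
  }
  out <- acc / wts
  if (inherits(volume, "volume3d"))
    volume3d(out, voxel_um = vol_voxel(volume))
  else out
}

#' Blending weight field of the tiling scheme
#'
#' Exposes the accumulated (pre-normalization) linear blend weights used
#' by [apply_tiled()] so their voxelwise sum can be inspected directly.
#'
#' @param vol_shape volume shape (nz, ny, nx).
#' @inheritParams apply_tiled
#' @return numeric array of summed weights (1 everywhere when tiles abut
#'   the scheme's design).
#' @export
tile_weight_field <- function(vol_shape, tile_shape = c(256, 256, 256),
                              overlap = 32) {
  d <- as.integer(vol_shape)
  tl <- pmin(rep(as.integer(tile_shape), length.out = 3), d)
  ov <- rep(as.integer(overlap), length.out = 3)
  ov <- pmin(ov, tl - 1L)
  oz <- tile_origins(d[1], tl[1], ov[1])
  oy <- tile_origins(d[2], tl[2], ov[2])
  ox <- tile_origins(d[3], tl[3], ov[3])
  wts <- array(0, d)
  for (z0 in oz) for (y0 in oy) for (x0 in ox) {
    iz <- z0:(z0 + tl[1] - 1L); iy <- y0:(y0 + tl[2] - 1L)
    ix <- x0:(x0 + tl[3] - 1L)
    wz <- ramp_profile(tl[1], ov[1], z0 == oz[1], z0 == oz[length(oz)])
    wy <- ramp_profile(tl[2], ov[2], y0 == oy[1], y0 == oy[length(oy)])
    wx <- ramp_profile(tl[3], ov[3], x0 == ox[1], x0 == ox[length(ox)])
    wts[iz, iy, ix] <- wts[iz, iy, ix] + outer(outer(wz, wy), wx)
  }
  wts
}

#' A trivial identity model (testing / plumbing checks)
#' @return a model whose prediction is its input.
#' @export
identity_model <- function() structure(list(), class = "identity_model")

#' @export
predict.identity_model <- function(object, volume, ...) vol_data(volume)
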