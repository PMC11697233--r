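# Training-corpus construction: aberrate ground-truth volumes with sampled
# aberrations, extract shallow subvolumes, patchify, and keep a manifest
# recording full provenance (seed, coefficients, RMS, SNR, file paths).

#' Build (ground truth, aberrated) training pairs
#'
#' For each source volume, samples `n_aberrations_per` independent
#' aberrations under `profile`, degrades the source through the
#' corresponding modified OTF, optionally adds Poisson noise at
#' `snr_target`, and records every pair in a manifest. With `out_dir` set,
#' volumes are written as 32-bit float TIFFs (ground truths once per
#' source, aberrated volumes once per pair); otherwise volumes are
#' returned in memory.
#'
#' @param sources list of ground-truth [volume3d()]s matching the config
#'   grid.
#' @param n_aberrations_per aberrations sampled per source (>= 1).
#' @param profile a [bounds_profile()] (its `mode`/`amplitude` control
#'   bounded vs fixed-RMS normalization).
#' @param config an [optical_config()] whose grid matches the sources.
#' @param snr_target Poisson-noise SNR per pair, or `NULL` for noise-free.
#' @param rng_seed master seed; every pair's sampling seed derives from it.
#' @param out_dir output directory, or `NULL` to keep volumes in memory.
#' @return a `training_manifest`: data.frame of per-pair records with
#'   attributes `config`, `profile` and (in-memory mode) `volumes`.
#' @export
make_training_pairs <- function(sources, n_aberrations_per, profile, config,
                                snr_target = NULL, rng_seed = NULL,
                                out_dir = NULL) {
  if (length(sources) < 1) stop("need at least one source volume")
  if (n_aberrations_per < 1) stop("n_aberrations_per must be >= 1")
  stopifnot(inherits(profile, "bounds_profile"),
            inherits(config, "optical_config"))
  n_pairs <- length(sources) * n_aberrations_per
  seeds <- derive_seeds(if (is.null(rng_seed)) 1L else rng_seed, 2L * n_pairs)
  ipsf <- psf_from_pupil(config, NULL)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  rec <- vector("list", n_pairs)
  volumes <- if (is.null(out_dir)) vector("list", n_pairs) else NULL
  pair <- 0L
  for (si in seq_along(sources)) {
    src <- as_vol3d(sources[[si]])
    gt_path <- NA_character_
    if (!is.null(out_dir)) {
      gt_path <- file.path(out_dir, sprintf("gt_%03d.tif", si))
      write_volume(src, gt_path)
    }
    for (ai in seq_len(n_aberrations_per)) {
      pair <- pair + 1L
      cseed <- seeds[2L * pair - 1L]
      nseed <- seeds[2L * pair]
      coeffs <- sample_coefficients(profile, rng_seed = cseed)
      ab <- degrade(src, motf = modified_otf(ipsf,
                                             psf_from_pupil(config, coeffs)))
      if (!is.null(snr_target))
        ab <- add_poisson_noise(ab, snr_target, rng_seed = nseed)
      ab_path <- NA_character_
      if (!is.null(out_dir)) {
        ab_path <- file.path(out_dir, sprintf("ab_%03d_%02d.tif", si, ai))
        write_volume(ab, ab_path)
      } else {
        volumes[[pair]] <- list(gt = src, aberrated = ab)
      }
      rec[[pair]] <- data.frame(
        pair_id = pair, source_id = si, aberration_id = ai,
        rng_seed = cseed, noise_seed = if (is.null(snr_target)) NA_integer_
                                       else nseed,
        coeffs_rad = I(list(coeffs)), rms_rad = zernike_rms(coeffs),
        snr_target = if (is.null(snr_target)) NA_real_ else snr_target,
        gt_path = gt_path, aberrated_path = ab_path)
    }
  }
  manifest <- do.call(rbind, rec)
  attr(manifest, "config") <- config
  attr(manifest, "profile") <- profile
  attr(manifest, "volumes") <- volumes
  class(manifest) <- c("training_manifest", "data.frame")
  manifest
}

#' Write a training manifest to JSON
#' @param manifest a `training_manifest` (file-backed, from
#'   [make_training_pairs()] with `out_dir`).
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    list(pair_id = r$pair_id, source_id = r$source_id,
         aberration_id = r$aberration_id, rng_seed = r$rng_seed,
         noise_seed = r$noise_seed, coeffs_rad = r$coeffs_rad[[1]],
         rms_rad = r$rms_rad, snr_target = r$snr_target,
         gt_path = r$gt_path, aberrated_path = r$aberrated_path)
  })
  jsonlite::write_json(list(pairs = recs), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a training manifest from JSON
#' @param path file written by [write_manifest()].
#' @return a `training_manifest` data.frame.
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path)
  rec <- lapply(obj$pairs, function(r) {
    data.frame(pair_id = r$pair_id, source_id = r$source_id,
               aberration_id = r$aberration_id, rng_seed = r$rng_seed,
               noise_seed = if (is.null(r$noise_seed)) NA_integer_
                            else r$noise_seed,
               coeffs_rad = I(list(as.numeric(unlist(r$coeffs_rad)))),
               rms_rad = r$rms_rad,
               snr_target = if (is.null(r$snr_target)) NA_real_
                            else r$snr_target,
               gt_path = as.character(r$gt_path),
               aberrated_path = as.character(r$aberrated_path))
  })
  manifest <- do.call(rbind, rec)
  class(manifest) <- c("training_manifest", "data.frame")
  manifest
}

#' Extract a shallow (near-objective) subvolume
#'
#' Crops the z-range closest to the detection objective, where images are
#' near diffraction-limited and serve as restoration ground truth. The
#' window is half-open, 0-based: planes `z_start` .. `z_end - 1`;
#' fractional windows are floored to whole planes.
#'
#' @param stack a [volume3d()] (z = depth from the shallow side).
#' @param window numeric length-2 `(z_start, z_end)`: plane indices when
#'   integer-valued and >= 1, or fractions of the stack when both in [0,1].
#' @return the cropped [volume3d()]; attribute `"z_range"` records the
#'   source planes (1-based, inclusive).
#' @export
extract_shallow_subvolume <- function(stack, window) {
  a <- vol_data(stack)
  nz <- dim(a)[1]
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be (z_start, z_end) with z_end > z_start")
  if (all(window >= 0) && all(window <= 1) && window[2] <= 1) {
    z1 <- floor(window[1] * nz); z2 <- floor(window[2] * nz)
  } else {
    z1 <- window[1]; z2 <- window[2]
  }
  if (z1 < 0 || z2 > nz || z2 <= z1) stop("window outside the stack")
  planes <- (z1 + 1):z2
  out <- volume3d(a[planes, , , drop = FALSE], voxel_um = vol_voxel(stack))
  attr(out, "z_range") <- c(planes[1], planes[length(planes)])
  out
}

#' Split a volume into patches
#'
#' Either a regular grid (given `stride`) or `count` uniformly random
#' patch origins (seedable). Coordinates are 1-based origins (z, y, x) so
#' patches can be reassembled exactly.
#'
#' @param volume a [volume3d()].
#' @param patch_shape (pz, py, px), default 64^3.
#' @param stride step between grid origins (scalar or length 3); default
#'   the patch shape (non-overlapping tiling).
#' @param count number of random patches instead of a grid.
#' @param rng_seed seed for random-count mode.
#' @return list with `patches` (list of arrays) and `coords` (matrix of
#'   1-based origins).
#' @export
patchify <- function(volume, patch_shape = c(64, 64, 64), stride = NULL,
                     count = NULL, rng_seed = NULL) {
  a <- vol_data(volume)
  d <- dim(a)
  p <- rep(as.integer(patch_shape), length.out = 3)
  if (any(p > d)) stop("patch larger than the volume")
  if (!is.null(count)) {
    coords <- with_seed(rng_seed, {
      t(vapply(seq_len(count), function(i)
        vapply(1:3, function(ax)
          sample.int(d[ax] - p[ax] + 1L, 1L), integer(1)), integer(3)))
    })
  } else {
    if (is.null(stride)) stride <- p
    s <- rep(as.integer(stride), length.out = 3)
    origins <- lapply(1:3, function(ax) {
      o <- seq(1L, d[ax] - p[ax] + 1L, by = s[ax])
      # always include the last valid origin so the grid covers the volume
      if (o[length(o)] != d[ax] - p[ax] + 1L) o <- c(o, d[ax] - p[ax] + 1L)
      o
    })
    coords <- as.matrix(expand.grid(z = origins[[1]], y = origins[[2]],
                                    x = origins[[3]]))
  }
  patches <- lapply(seq_len(nrow(coords)), function(i) {
    o <- coords[i, ]
    a[o[1]:(o[1] + p[1] - 1L), o[2]:(o[2] + p[2] - 1L),
      o[3]:(o[3] + p[3] - 1L), drop = FALSE]
  })
  list(patches = patches, coords = coords, patch_shape = p)
}

#' Reassemble patches into a volume
#'
#' Overlapping voxels are averaged; with a non-overlapping grid this
#' reproduces the original volume exactly.
#'
#' @param patches,coords,patch_shape as returned by [patchify()].
#' @param out_shape target volume shape (nz, ny, nx).
#' @return a 3D array.
#' @export
unpatchify <- function(patches, coords, patch_shape, out_shape) {
  acc <- array(0, out_shape)
  wt <- array(0, out_shape)
  p <- patch_shape
  for (i in seq_along(patches)) {
    o <- coords[i, ]
    iz <- o[1]:(o[1] + p[1] - 1L); iy <- o[2]:(o[2] + p[2] - 1L)
    ix <- o[3]:(o[3] + p[3] - 1L)
    acc[iz, iy, ix] <- acc[iz, iy, ix] + patches[[i]]
    wt[iz, iy, ix] <- wt[iz, iy, ix] + 1
  }
  if (any(wt == 0)) warning("reassembled volume has uncovered voxels")
  acc / pmax(wt, 1)
}
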