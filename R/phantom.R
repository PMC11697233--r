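# 3D test phantoms: randomly posed dots, lines (finite cylinders), circles
# (rings/tori), spheres, and spherical shells on a voxel grid.
#
# Rasterization is anti-aliased by 2x supersampling within each object's
# bounding box: each voxel is tested at 8 subvoxel points and the inside
# fraction becomes the occupancy. Objects combine by voxelwise maximum.

#' Specification for a random 3D phantom
#'
#' @param grid_shape voxel grid (nz, ny, nx), default 256^3.
#' @param voxel_um voxel size (dz, dy, dx) in micrometers.
#' @param counts named integer vector giving the number of each structure:
#'   `dots`, `lines`, `circles`, `spheres`, `shells`.
#' @param size_ranges named list of per-type size ranges, in voxels:
#'   `dot_radius`, `line_radius`, `line_length`, `circle_radius`,
#'   `circle_tube`, `sphere_radius`, `shell_radius`, `shell_thickness`.
#' @param intensity_range per-object intensity drawn uniformly from this
#'   range (arbitrary units).
#' @param rng_seed integer seed; generation is deterministic given it.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(256, 256, 256),
                         voxel_um = c(0.13, 0.13, 0.13),
                         counts = c(dots = 80, lines = 30, circles = 15,
                                    spheres = 15, shells = 15),
                         size_ranges = list(),
                         intensity_range = c(0.5, 1.0),
                         rng_seed = NULL) {
  defaults <- list(dot_radius = c(1, 2), line_radius = c(1, 3),
                   line_length = c(20, 80), circle_radius = c(5, 15),
                   circle_tube = c(1, 2), sphere_radius = c(4, 12),
                   shell_radius = c(5, 14), shell_thickness = c(1, 3))
  size_ranges <- utils::modifyList(defaults, size_ranges)
  full <- c(dots = 0L, lines = 0L, circles = 0L, spheres = 0L, shells = 0L)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0)) stop("structure counts must be non-negative")
  if (any(grid_shape < 8)) stop("grid too small")
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_um = as.numeric(voxel_um), counts = full,
                 size_ranges = size_ranges,
                 intensity_range = as.numeric(intensity_range),
                 rng_seed = rng_seed),
            class = "phantom_spec")
}

# uniform random unit vector (3D)
runif_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# Rasterize one object into vol (by reference semantics via return).
# inside_fn(x, y, z) takes voxel-unit coordinates relative to the object
# center and returns logical. extent = half-size of the bounding box.
rasterize_object <- function(vol, center, extent, inside_fn, intensity) {
  d <- dim(vol)
  # bounding box in (z, y, x) voxel indices
  lo <- pmax(floor(center - extent - 1), 1)
  hi <- pmin(ceiling(center + extent + 1), d)
  if (any(lo > hi)) return(vol)
  zi <- lo[1]:hi[1]; yi <- lo[2]:hi[2]; xi <- lo[3]:hi[3]
  nz <- length(zi); ny <- length(yi); nx <- length(xi)
  # 2x supersampling: 8 offsets at +-0.25 voxel
  occ <- array(0, c(nz, ny, nx))
  for (oz in c(-0.25, 0.25)) for (oy in c(-0.25, 0.25))
    for (ox in c(-0.25, 0.25)) {
      Z <- array(zi + oz - center[1], c(nz, ny, nx))
      Y <- aperm(array(yi + oy - center[2], c(ny, nz, nx)), c(2, 1, 3))
      X <- aperm(array(xi + ox - center[3], c(nx, ny, nz)), c(3, 2, 1))
      occ <- occ + inside_fn(X, Y, Z)
    }
  occ <- occ / 8
  blk <- vol[zi, yi, xi]
  vol[zi, yi, xi] <- pmax(blk, occ * intensity)
  vol
}

#' Generate a random 3D phantom volume
#'
#' Places the requested number of each structure type at uniformly random
#' positions and orientations, anti-aliased onto the grid. Object placement
#' retries (up to 100 times each) when a sampled pose does not fit inside
#' the grid; persistent failure raises an error naming the structure type.
#'
#' @param spec a [phantom_spec()].
#' @return a [volume3d()]; attribute `"objects"` holds the generation log,
#'   one row per placed object (type, center, size parameters, intensity).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$rng_seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  d <- spec$grid_shape
  vol <- array(0, d)
  sr <- spec$size_ranges
  log <- list()
  place <- function(type, extent_fn, inside_builder) {
    n <- spec$counts[[type]]
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in 1:100) {
        params <- inside_builder()
        ext <- extent_fn(params)
        if (any(2 * ext + 2 >= d)) next   # object cannot fit
        center <- stats::runif(3, ext + 1, d - ext - 1)
        intensity <- stats::runif(1, spec$intensity_range[1],
                                  spec$intensity_range[2])
        vol <<- rasterize_object(vol, center, ext, params$fn, intensity)
        log[[length(log) + 1]] <<- data.frame(
          type = type, cz = center[1], cy = center[2], cx = center[3],
          size1 = params$size1, size2 = params$size2,
          intensity = intensity)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place structure of type '", type,
             "' inside the grid after 100 attempts")
    }
  }

  place("dots", function(p) rep(p$size1, 3), function() {
    r <- stats::runif(1, sr$dot_radius[1], sr$dot_radius[2])
    list(size1 = r, size2 = NA,
         fn = function(X, Y, Z) X^2 + Y^2 + Z^2 <= r^2)
  })
  place("spheres", function(p) rep(p$size1, 3), function() {
    r <- stats::runif(1, sr$sphere_radius[1], sr$sphere_radius[2])
    list(size1 = r, size2 = NA,
         fn = function(X, Y, Z) X^2 + Y^2 + Z^2 <= r^2)
  })
  place("shells", function(p) rep(p$size1, 3), function() {
    r <- stats::runif(1, sr$shell_radius[1], sr$shell_radius[2])
    t <- min(stats::runif(1, sr$shell_thickness[1], sr$shell_thickness[2]), r)
    list(size1 = r, size2 = t, fn = function(X, Y, Z) {
      d2 <- X^2 + Y^2 + Z^2
      d2 <= r^2 & d2 >= (r - t)^2
    })
  })
  place("lines", function(p) rep(p$size1 / 2 + p$size2, 3), function() {
    len <- stats::runif(1, sr$line_length[1], sr$line_length[2])
    rad <- stats::runif(1, sr$line_radius[1], sr$line_radius[2])
    u <- runif_unit_vector()                 # (x, y, z) components
    list(size1 = len, size2 = rad, fn = function(X, Y, Z) {
      t <- pmin(pmax(X * u[1] + Y * u[2] + Z * u[3], -len / 2), len / 2)
      (X - t * u[1])^2 + (Y - t * u[2])^2 + (Z - t * u[3])^2 <= rad^2
    })
  })
  place("circles", function(p) rep(p$size1 + p$size2, 3), function() {
    R <- stats::runif(1, sr$circle_radius[1], sr$circle_radius[2])
    tb <- stats::runif(1, sr$circle_tube[1], sr$circle_tube[2])
    u <- runif_unit_vector()                 # ring-plane normal
    list(size1 = R, size2 = tb, fn = function(X, Y, Z) {
      par <- X * u[1] + Y * u[2] + Z * u[3]
      perp2 <- X^2 + Y^2 + Z^2 - par^2
      (sqrt(pmax(perp2, 0)) - R)^2 + par^2 <= tb^2
    })
  })

  out <- volume3d(vol, voxel_um = spec$voxel_um)
  attr(out, "objects") <- if (length(log)) do.call(rbind, log) else
    data.frame(type = character(), cz = numeric(), cy = numeric(),
               cx = numeric(), size1 = numeric(), size2 = numeric(),
               intensity = numeric())
  out
}

#' Blur a phantom with a PSF (circular FFT convolution)
#'
#' The PSF (origin-centered, any size up to the volume's) is zero-padded to
#' the volume grid and applied as a circular convolution; total intensity
#' is preserved since the PSF sums to 1.
#'
#' @param phantom a [volume3d()].
#' @param psf an origin-centered PSF ([volume3d()], unit sum).
#' @return blurred [volume3d()].
#' @export
blur_with_psf <- function(phantom, psf) {
  a <- vol_data(phantom)
  k <- vol_data(psf)
  if (any(dim(k) > dim(a))) stop("PSF larger than the volume")
  k <- pad_center(k, dim(a))
  out <- Re(ifftn(fftn(a) * fftn(ifftshift3(k))))
  dim(out) <- dim(a)
  volume3d(pmax(out, 0), voxel_um = vol_voxel(phantom))
}
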