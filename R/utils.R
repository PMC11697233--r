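#' @importFrom stats predict
#' @keywords internal
"_PACKAGE"

# Shared numerical helpers: FFT layout, seeded RNG scoping, 3D volumes.
#
# Array convention used throughout the package: dim 1 = z (depth, plane index
# increasing away from the detection objective), dim 2 = y, dim 3 = x.
# PSFs are stored origin-centered (peak at the geometric center voxel,
# index floor(dim/2) + 1 on each axis); frequency-space operations move them
# to the FFT-native corner layout with ifftshift3().

#' Construct a 3D volume with physical voxel size
#'
#' A `volume3d` is a plain numeric 3D array (z, y, x) carrying its voxel
#' size in micrometers as an attribute. All package operations accept either
#' a `volume3d` or a bare 3D array.
#'
#' @param data numeric 3D array ordered (z, y, x).
#' @param voxel_um numeric length-3, voxel size (dz, dy, dx) in micrometers.
#' @return a `volume3d` object.
#' @export
volume3d <- function(data, voxel_um = c(0.13, 0.13, 0.13)) {
  if (length(dim(data)) != 3L)
    stop("expected 3D stack, got array with ", length(dim(data)), " dimension(s)")
  if (length(voxel_um) != 3L || any(voxel_um <= 0))
    stop("voxel_um must be three positive values (dz, dy, dx)")
  if (!all(is.finite(data)))
    stop("volume contains non-finite values")
  structure(data, voxel_um = as.numeric(voxel_um), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x)
  v <- attr(x, "voxel_um")
  cat(sprintf("volume3d: %d x %d x %d voxels (z,y,x), voxel %s um\n",
              d[1], d[2], d[3], paste(signif(v, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%g, %g], mean %g\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

# strip class/attrs down to a bare array (keeps only dim)
vol_data <- function(v) {
  a <- unclass(v)
  attributes(a) <- list(dim = dim(a))
  a
}

vol_voxel <- function(v, default = c(0.13, 0.13, 0.13)) {
  vx <- attr(v, "voxel_um")
  if (is.null(vx)) default else vx
}

as_vol3d <- function(v, voxel_um = NULL) {
  if (inherits(v, "volume3d") && is.null(voxel_um)) return(v)
  volume3d(if (is.null(dim(v))) stop("not an array") else vol_data(v),
           voxel_um = if (is.null(voxel_um)) vol_voxel(v) else voxel_um)
}

# ---- FFT helpers ------------------------------------------------------------

fftn <- function(a) stats::fft(a)

ifftn <- function(a) stats::fft(a, inverse = TRUE) / length(a)

# FFT sample frequencies (cycles per unit), same ordering as stats::fft
fft_freq <- function(n, d = 1) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2)):-1)
  k / (n * d)
}

# circularly shift vector of indices so that the center lands at position 1
shift_idx <- function(n, inverse = FALSE) {
  h <- if (inverse) floor(n / 2) else ceiling(n / 2)
  c((h + 1):n, 1:h)
}

# move origin-centered array to FFT-native corner layout
ifftshift3 <- function(a) {
  d <- dim(a)
  a[shift_idx(d[1], inverse = TRUE), shift_idx(d[2], inverse = TRUE),
    shift_idx(d[3], inverse = TRUE), drop = FALSE]
}

# move FFT-native corner layout to origin-centered
fftshift3 <- function(a) {
  d <- dim(a)
  a[shift_idx(d[1]), shift_idx(d[2]), shift_idx(d[3]), drop = FALSE]
}

fftshift2 <- function(a) {
  d <- dim(a)
  a[shift_idx(d[1]), shift_idx(d[2]), drop = FALSE]
}

# ---- seeded evaluation ------------------------------------------------------

# Evaluate expr under a locally-set RNG state; restores the caller's state.
# All stochastic operations in the package route their rng_seed through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a stream of child seeds from one master seed, all < 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# pad a small origin-centered kernel into a larger grid (still centered)
pad_center <- function(kernel, out_dim) {
  kd <- dim(kernel)
  if (any(kd > out_dim)) stop("kernel larger than target grid")
  if (all(kd == out_dim)) return(kernel)
  out <- array(0, out_dim)
  ctr_o <- floor(out_dim / 2) + 1L
  ctr_k <- floor(kd / 2) + 1L
  lo <- ctr_o - (ctr_k - 1L)
  hi <- lo + kd - 1L
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- kernel
  out
}
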