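# Zernike polynomial machinery (ANSI single-index convention).
#
# Modes are orthonormal over the unit disk (unit RMS), so the Euclidean norm
# of a coefficient vector (piston/tilt excluded) equals the RMS wavefront
# distortion in radians. Coefficient vectors are stored as plain numeric
# vectors indexed ANSI 0..M; R's 1-based element i holds ANSI index i-1.

#' Convert an ANSI Zernike index to (radial order, azimuthal frequency)
#'
#' The ANSI single-index convention maps the pair (n, m) -- with
#' n - |m| even and |m| <= n -- to j = (n(n+2) + m) / 2. Index 4 is defocus,
#' index 12 primary spherical aberration.
#'
#' @param ansi_index non-negative integer (vectorized).
#' @return a list with integer vectors `n` and `m`.
#' @seealso [nm_to_ansi()], [max_index_for_order()]
#' @export
ansi_to_nm <- function(ansi_index) {
  j <- as.integer(ansi_index)
  if (any(j < 0)) stop("ansi_index must be non-negative")
  n <- floor((sqrt(8 * j + 1) - 1) / 2)
  m <- 2L * j - as.integer(n * (n + 2))
  list(n = as.integer(n), m = as.integer(m))
}

#' Convert (radial order, azimuthal frequency) to the ANSI index
#' @param n radial order (non-negative integer).
#' @param m azimuthal frequency; |m| <= n and n - |m| even.
#' @return integer ANSI index.
#' @export
nm_to_ansi <- function(n, m) {
  if (any(abs(m) > n) || any((n - abs(m)) %% 2 != 0))
    stop("invalid (n, m): need |m| <= n with n - |m| even")
  as.integer((n * (n + 2) + m) / 2)
}

#' Largest ANSI index of a given radial order
#'
#' Radial order `q` contains modes up to ANSI index (q+1)(q+2)/2 - 1; e.g.
#' order 3 ends at index 9 and order 4 at index 14, the order used for all
#' experimental aberration syntheses in this package's defaults.
#'
#' @param radial_order non-negative integer.
#' @return integer, the maximal ANSI index M of that order.
#' @export
max_index_for_order <- function(radial_order) {
  q <- as.integer(radial_order)
  if (any(q < 0)) stop("radial_order must be non-negative")
  as.integer((q + 1) * (q + 2) / 2 - 1)
}

# Radial polynomial R_n^|m|(r), standard finite sum.
zernike_radial <- function(n, m_abs, r) {
  out <- 0
  for (k in 0:((n - m_abs) / 2)) {
    out <- out + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + m_abs) / 2 - k) *
         factorial((n - m_abs) / 2 - k)) * r^(n - 2 * k)
  }
  out
}

#' Evaluate one orthonormal Zernike mode
#'
#' Uses the unit-RMS (orthonormal) normalization: sqrt(n+1) R_n^0(r) for
#' m = 0, sqrt(2(n+1)) R_n^|m|(r) cos(m theta) for m > 0 and
#' sin(|m| theta) for m < 0. With this convention the disk average of
#' phi_m^2 is 1, so coefficient norms are wavefront RMS values.
#'
#' @param ansi_index non-negative integer mode index (scalar).
#' @param r radius in [0, 1] (vectorized).
#' @param theta azimuth in radians (vectorized, recycled against r).
#' @return numeric vector of mode values.
#' @export
evaluate_mode <- function(ansi_index, r, theta) {
  if (any(r < 0 | r > 1)) stop("r must lie in [0, 1]")
  nm <- ansi_to_nm(ansi_index)
  n <- nm$n; m <- nm$m
  norm <- if (m == 0) sqrt(n + 1) else sqrt(2 * (n + 1))
  rad <- zernike_radial(n, abs(m), r)
  ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(abs(m) * theta) else 1
  norm * rad * ang
}

#' Assemble a wavefront phase map from Zernike coefficients
#'
#' Sums c_m phi_m(r, theta) over all modes with nonzero coefficients.
#' Coefficient element i of the vector is the ANSI index i-1 mode.
#'
#' @param coeffs numeric vector of Zernike coefficients (radians), ANSI
#'   indices 0..M in order.
#' @param r,theta polar pupil coordinates (r normalized to the pupil edge);
#'   arrays of matching shape.
#' @return phase map (radians), same shape as `r`.
#' @export
wavefront <- function(coeffs, r, theta) {
  stopifnot(length(coeffs) >= 1)
  phase <- if (is.null(dim(r))) numeric(length(r)) else array(0, dim(r))
  nz <- which(coeffs != 0)
  for (i in nz) {
    phase <- phase + coeffs[i] * evaluate_mode(i - 1L, r, theta)
  }
  phase
}

#' RMS wavefront distortion of a coefficient vector
#'
#' Euclidean norm over ANSI indices m = 3..M; piston and the two tilts
#' (indices 0, 1, 2) shift or translate the image without degrading it and
#' are excluded.
#'
#' @param coeffs numeric coefficient vector, ANSI indices 0..M.
#' @return non-negative RMS in radians.
#' @export
zernike_rms <- function(coeffs) {
  if (length(coeffs) < 4) return(0)
  sqrt(sum(coeffs[-(1:3)]^2))
}

#' Coefficient bounds profile for semi-random aberration sampling
#'
#' Defines per-mode upper bounds T_m with piston/tilt forced to zero, plus
#' how a sampled vector is normalized: `"upper_bounded"` rescales by
#' amplitude / RMS_T (so amplitude is a *maximum* RMS), `"fixed_rms"`
#' rescales by amplitude / RMS_c (so every draw has exactly that RMS).
#'
#' @param bounds numeric vector of non-negative bounds T_m, ANSI indices
#'   0..M; elements 1..3 (piston, tilts) must be 0.
#' @param mode `"upper_bounded"` or `"fixed_rms"`; `NULL` to sample the raw
#'   bounded coefficients without rescaling.
#' @param amplitude target RMS amplitude in radians (maximum RMS for
#'   `"upper_bounded"`, exact RMS for `"fixed_rms"`); ignored when `mode`
#'   is `NULL`.
#' @return a `bounds_profile` object.
#' @export
bounds_profile <- function(bounds, mode = NULL, amplitude = NULL) {
  bounds <- as.numeric(bounds)
  if (length(bounds) < 4) stop("bounds must cover ANSI indices 0..3 at least")
  if (any(bounds < 0)) stop("bounds must be non-negative")
  if (any(bounds[1:3] != 0)) stop("piston and tilt bounds (indices 0..2) must be 0")
  if (!is.null(mode)) {
    mode <- match.arg(mode, c("upper_bounded", "fixed_rms"))
    if (is.null(amplitude) || amplitude <= 0)
      stop("amplitude must be a positive RMS (radians) when mode is set")
  }
  structure(list(bounds = bounds, mode = mode, amplitude = amplitude),
            class = "bounds_profile")
}

#' Standard simulation bounds for mixed-mode aberrations
#'
#' Bounds of 1.5 rad on the low-order modes most prominent in real samples
#' (oblique/vertical astigmatism m = 3, 5; defocus m = 4; primary spherical
#' m = 12) and 0.5 rad on every other mode up to the chosen radial order;
#' piston and tilt excluded.
#'
#' @param radial_order maximum Zernike radial order (default 4, i.e. M = 14).
#' @inheritParams bounds_profile
#' @return a `bounds_profile`.
#' @export
simulation_bounds <- function(radial_order = 4, mode = NULL, amplitude = NULL) {
  M <- max_index_for_order(radial_order)
  b <- rep(0.5, M + 1)
  b[1:3] <- 0
  b[c(3, 4, 5, 12) + 1] <- 1.5
  bounds_profile(b, mode = mode, amplitude = amplitude)
}

#' Experimental-dataset bounds (defocus and spherical emphasized)
#'
#' 0.5 rad on all modes with an extra 1.0 rad on defocus (m = 4) and primary
#' spherical (m = 12), matching the contamination most often seen in
#' acquired data; piston/tilt zero.
#'
#' @inheritParams simulation_bounds
#' @return a `bounds_profile`.
#' @export
experimental_bounds <- function(radial_order = 4, mode = NULL, amplitude = NULL) {
  M <- max_index_for_order(radial_order)
  b <- rep(0.5, M + 1)
  b[1:3] <- 0
  b[c(4, 12) + 1] <- 1.5
  bounds_profile(b, mode = mode, amplitude = amplitude)
}

#' Defocus-only bounds profile
#'
#' All bounds zero except 1.5 rad on defocus (m = 4); used to synthesize
#' pure-defocus training corpora.
#'
#' @inheritParams simulation_bounds
#' @return a `bounds_profile`.
#' @export
defocus_bounds <- function(radial_order = 4, mode = NULL, amplitude = NULL) {
  M <- max_index_for_order(radial_order)
  b <- rep(0, M + 1)
  b[4 + 1] <- 1.5
  bounds_profile(b, mode = mode, amplitude = amplitude)
}

# RMS_T: the bound vector's own RMS over m = 3..M
bounds_rms <- function(profile) zernike_rms(profile$bounds)

#' Sample a semi-random aberration under a bounds profile
#'
#' Each coefficient is drawn independently and uniformly on [-T_m, T_m]
#' (piston/tilt stay 0). If the profile carries a normalization mode the
#' draw is then rescaled: `"upper_bounded"` multiplies by amplitude / RMS_T
#' so the amplitude is an upper bound on the resulting RMS; `"fixed_rms"`
#' multiplies by amplitude / RMS_c so the result has exactly that RMS.
#'
#' @param profile a [bounds_profile()].
#' @param rng_seed optional integer seed; the draw is deterministic given it.
#' @return numeric coefficient vector (radians), ANSI indices 0..M.
#' @export
sample_coefficients <- function(profile, rng_seed = NULL) {
  stopifnot(inherits(profile, "bounds_profile"))
  b <- profile$bounds
  coeffs <- with_seed(rng_seed, stats::runif(length(b), -b, b))
  coeffs[b == 0] <- 0
  if (!is.null(profile$mode)) {
    coeffs <- switch(profile$mode,
      upper_bounded = rescale_to_rms(coeffs, profile$amplitude,
                                     normalizer = "by_bound_rms",
                                     profile = profile),
      fixed_rms = rescale_to_rms(coeffs, profile$amplitude,
                                 normalizer = "by_coeff_rms"))
  }
  coeffs
}

#' Rescale a coefficient vector to a target RMS amplitude
#'
#' `by_coeff_rms` multiplies by target_rms / RMS_c, giving exactly the
#' target RMS. `by_bound_rms` multiplies by target_rms / RMS_T (the RMS of
#' the profile's bound vector), so the target is a *maximum* RMS: any
#' sampled vector satisfies RMS_c <= RMS_T, hence the result is <= target.
#'
#' @param coeffs numeric coefficient vector (ANSI 0..M).
#' @param target_rms positive target amplitude in radians.
#' @param normalizer `"by_coeff_rms"` or `"by_bound_rms"`.
#' @param profile the [bounds_profile()] whose bounds define RMS_T
#'   (required for `"by_bound_rms"`).
#' @return rescaled coefficient vector.
#' @export
rescale_to_rms <- function(coeffs, target_rms,
                           normalizer = c("by_coeff_rms", "by_bound_rms"),
                           profile = NULL) {
  normalizer <- match.arg(normalizer)
  if (target_rms <= 0) stop("target_rms must be positive")
  if (normalizer == "by_coeff_rms") {
    rc <- zernike_rms(coeffs)
    if (rc == 0) stop("degenerate aberration: zero RMS cannot be rescaled")
    coeffs * (target_rms / rc)
  } else {
    if (is.null(profile)) stop("by_bound_rms requires the bounds profile")
    rt <- bounds_rms(profile)
    if (rt == 0) stop("bounds profile has zero RMS_T")
    coeffs * (target_rms / rt)
  }
}

#' Coefficients for a single named aberration mode at fixed RMS
#'
#' Defocus puts the full amplitude on c_4 and spherical on c_12. The paired
#' modes split the amplitude between their two ANSI partners --
#' astigmatism (3, 5), coma (7, 8), trefoil (6, 9) -- as
#' amplitude * (cos split_angle, sin split_angle), so the joint RMS is the
#' amplitude for any split.
#'
#' @param mode_name one of `"defocus"`, `"astigmatism"`, `"coma"`,
#'   `"trefoil"`, `"spherical"`.
#' @param amplitude positive RMS amplitude (radians).
#' @param split_angle orientation split for the paired modes (radians);
#'   default drawn uniformly on [0, 2*pi) (seedable via `rng_seed`).
#' @param max_index highest ANSI index of the returned vector (default 14).
#' @param rng_seed optional seed for the default split angle.
#' @return numeric coefficient vector, ANSI indices 0..max_index.
#' @export
single_mode_coefficients <- function(mode_name, amplitude, split_angle = NULL,
                                     max_index = 14, rng_seed = NULL) {
  mode_name <- match.arg(mode_name,
    c("defocus", "astigmatism", "coma", "trefoil", "spherical"))
  if (amplitude <= 0) stop("amplitude must be positive")
  if (is.null(split_angle))
    split_angle <- with_seed(rng_seed, stats::runif(1, 0, 2 * pi))
  coeffs <- numeric(max_index + 1)
  set1 <- function(ansi, val) coeffs[ansi + 1] <<- val
  pair <- switch(mode_name,
    defocus = { set1(4, amplitude); NULL },
    spherical = { set1(12, amplitude); NULL },
    astigmatism = c(3, 5), coma = c(7, 8), trefoil = c(6, 9))
  if (!is.null(pair)) {
    set1(pair[1], amplitude * cos(split_angle))
    set1(pair[2], amplitude * sin(split_angle))
  }
  coeffs
}

#' Write Zernike coefficients to JSON
#' @param coeffs numeric coefficient vector (radians), ANSI order.
#' @param path output file path.
#' @export
write_coefficients <- function(coeffs, path) {
  jsonlite::write_json(list(ansi_convention = TRUE,
                            coeffs_rad = as.numeric(coeffs)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read Zernike coefficients from JSON
#' @param path file written by [write_coefficients()].
#' @return numeric coefficient vector.
#' @export
read_coefficients <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!isTRUE(obj$ansi_convention))
    stop("coefficient file does not declare the ANSI convention: ", path)
  as.numeric(obj$coeffs_rad)
}
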