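# Shared fixtures, built in code at test time.

# small light-sheet configuration matching the simulated instrument
# (1.1 NA water dipping, 0.532 um detection, 2 um sheet, 0.13 um voxels)
test_config <- function(n = 48) {
  optical_config(na = 1.1, wavelength_um = 0.532, medium_index = 1.33,
                 voxel_um = c(0.13, 0.13, 0.13), grid_shape = c(n, n, n),
                 sheet_fwhm_um = 2)
}

# reduced-scale phantom: same structure mix as the 256^3 default,
# counts scaled to keep a comparable workload per volume
test_phantom <- function(n = 48, seed = 1,
                         counts = c(dots = 6, lines = 3, circles = 2,
                                    spheres = 2, shells = 2)) {
  generate_phantom(phantom_spec(grid_shape = c(n, n, n), counts = counts,
                                rng_seed = seed))
}

# straight cylinder with a Gaussian cross-section (realistic vessel profile)
# axis: 1 = z, 2 = y, 3 = x
gauss_cylinder <- function(d = c(32, 32, 32), axis = 3, sigma = 1.5) {
  ctr <- (d + 1) / 2
  z <- slice.index(array(0, d), 1); y <- slice.index(array(0, d), 2)
  x <- slice.index(array(0, d), 3)
  r2 <- switch(axis,
               (y - ctr[2])^2 + (x - ctr[3])^2,
               (z - ctr[1])^2 + (x - ctr[3])^2,
               (z - ctr[1])^2 + (y - ctr[2])^2)
  exp(-r2 / (2 * sigma^2))
}

# shift an array along the y axis by k voxels (zero fill)
abind_shift <- function(a, k) {
  out <- array(0, dim(a))
  ny <- dim(a)[2]
  if (k > 0 && k < ny) out[, (k + 1):ny, ] <- a[, 1:(ny - k), ]
  out
}

# uniform random unit vectors (rows), fixed seed
random_unit_vectors <- function(k, seed = 1) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * k), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# quadrature grid covering the unit disk approximately uniformly in area
disk_quadrature <- function(n_r = 80, n_t = 160) {
  r <- sqrt((seq_len(n_r) - 0.5) / n_r)     # area-uniform radial nodes
  t <- (seq_len(n_t) - 0.5) / n_t * 2 * pi
  list(r = rep(r, times = n_t), theta = rep(t, each = n_r))
}
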