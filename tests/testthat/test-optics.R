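test_that("pupil grid geometry matches the configured aperture", {
  cfg <- test_config(48)
  g <- pupil_grid(cfg)
  expect_equal(g$r[1, 1], 0)                       # DC at grid origin
  expect_true(all(g$theta > -pi & g$theta <= pi))
  # pupil disk area fraction vs analytic value, 2% tolerance
  frac_obs <- mean(g$mask)
  frac_th <- pi * (cfg$na / cfg$wavelength_um)^2 *
    prod(cfg$voxel_um[2:3])
  expect_equal(frac_obs, frac_th, tolerance = 0.02)
  expect_error(optical_config(na = 1.1, voxel_um = c(0.3, 0.3, 0.3)),
               "Nyquist")
  expect_error(optical_config(na = 1.4, medium_index = 1.33), "na")
})

test_that("ideal PSF is centered, normalized and near the Airy width", {
  cfg <- test_config(48)
  psf <- psf_from_pupil(cfg)
  a <- vol_data(psf)
  expect_true(all(a >= 0))
  expect_equal(sum(a), 1)
  pk <- which(a == max(a), arr.ind = TRUE)
  expect_equal(as.integer(pk[1, ]), rep(25L, 3))   # floor(48/2) + 1
  # lateral FWHM vs 0.51 lambda / NA within 10%
  prof <- a[pk[1], pk[2], ]
  x <- (seq_along(prof) - pk[3]) * cfg$voxel_um[3]
  f <- stats::approxfun(x, prof - max(prof) / 2)
  fwhm <- stats::uniroot(f, c(0, 0.5))$root -
    stats::uniroot(f, c(-0.5, 0))$root
  expect_equal(fwhm, 0.51 * cfg$wavelength_um / cfg$na, tolerance = 0.1)
})

test_that("lateral PSF width shrinks monotonically with NA", {
  fwhm_at <- function(na) {
    cfg <- optical_config(na = na, grid_shape = c(16, 48, 48),
                          sheet_fwhm_um = 2)
    a <- vol_data(psf_from_pupil(cfg))
    pk <- which(a == max(a), arr.ind = TRUE)
    prof <- a[pk[1], pk[2], ]
    x <- (seq_along(prof) - pk[3]) * 0.13
    f <- stats::approxfun(x, prof - max(prof) / 2)
    stats::uniroot(f, c(0, 1))$root - stats::uniroot(f, c(-1, 0))$root
  }
  w <- vapply(c(0.6, 0.8, 1.1), fwhm_at, numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("defocus displaces the axial peak with mirror symmetry", {
  cfg <- test_config(48)
  c4 <- numeric(15); c4[4 + 1] <- 1.5
  p_pos <- vol_data(psf_from_pupil(cfg, c4))
  p_neg <- vol_data(psf_from_pupil(cfg, -c4))
  # per-plane peak intensity: defocus moves the brightest plane off focus
  ax_pos <- apply(p_pos, 1, max)
  zpk <- which.max(ax_pos)
  expect_true(zpk != 25)
  # c4 -> -c4 mirrors the axial profile about the focal plane (z = 0 at
  # index 25 on this even grid; index 1 has no mirror partner)
  ax_neg <- apply(p_neg, 1, max)
  expect_equal(ax_pos[2:48], ax_neg[rev(2:48)], tolerance = 1e-6)
})

test_that("modified OTF is 1 at DC, Hermitian, and identity for equal PSFs", {
  cfg <- test_config(32)
  ipsf <- psf_from_pupil(cfg)
  co <- sample_coefficients(simulation_bounds(mode = "fixed_rms",
                                              amplitude = 2), rng_seed = 3)
  apsf <- psf_from_pupil(cfg, co)
  m <- modified_otf(ipsf, apsf)
  expect_equal(m[1, 1, 1], 1 + 0i)
  # Hermitian symmetry: m(-k) = conj(m(k))
  idx <- function(n) c(1, n:2)
  m_rev <- m[idx(32), idx(32), idx(32)]
  expect_lt(max(Mod(m_rev - Conj(m))), 1e-6)
  vals <- Mod(modified_otf(ipsf, ipsf))
  expect_true(all(vals < 1e-9 | abs(vals - 1) < 1e-9))
  expect_error(modified_otf(ipsf, psf_from_pupil(test_config(16))),
               "shapes differ")
})

test_that("zero-aberration degradation is the identity on in-band volumes", {
  cfg <- test_config(48)
  ipsf <- psf_from_pupil(cfg)
  ph <- test_phantom(48, seed = 2)
  smooth <- blur_with_psf(blur_with_psf(ph, ipsf), ipsf)
  out <- degrade(smooth, cfg, rep(0, 15))
  relerr <- sqrt(sum((vol_data(out) - vol_data(smooth))^2) /
                   sum(vol_data(smooth)^2))
  expect_lt(relerr, 1e-5)
})

test_that("degradation preserves mean intensity and realness", {
  cfg <- test_config(48)
  ipsf <- psf_from_pupil(cfg)
  gt <- blur_with_psf(test_phantom(48, seed = 4), ipsf)
  co <- sample_coefficients(simulation_bounds(mode = "fixed_rms",
                                              amplitude = 2), rng_seed = 8)
  ab <- degrade(gt, cfg, co)
  expect_true(all(vol_data(ab) >= 0))
  expect_equal(mean(ab) / mean(gt), 1, tolerance = 0.01)
})

test_that("Poisson noise injection hits the target SNR", {
  cfg <- test_config(32)
  gt <- blur_with_psf(test_phantom(32, seed = 5,
                                   counts = c(dots = 4, lines = 2,
                                              circles = 1, spheres = 1,
                                              shells = 1)),
                      psf_from_pupil(cfg))
  n16 <- add_poisson_noise(gt, 16, rng_seed = 1)
  # above-threshold mean of the rescaled expectation equals snr^2
  a <- vol_data(gt)
  sig <- mean(a[a > 0.01 * max(a)])
  scaled <- a * 256 / sig
  expect_equal(mean(scaled[scaled > 0.01 * max(scaled)]), 256,
               tolerance = 1e-6)
  # measured SNR across independent noise draws matches the target
  snrs <- vapply(1:40, function(s)
    snr_estimate(add_poisson_noise(gt, 5, rng_seed = s)), numeric(1))
  expect_equal(mean(snrs), 5, tolerance = 0.1)
  expect_identical(vol_data(add_poisson_noise(gt, 16, rng_seed = 9)),
                   vol_data(add_poisson_noise(gt, 16, rng_seed = 9)))
  expect_error(add_poisson_noise(volume3d(array(0, c(8, 8, 8))), 16),
               "zero")
})
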