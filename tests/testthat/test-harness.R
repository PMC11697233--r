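test_that("tiled application of the identity model reproduces the input", {
  v <- volume3d(array(stats::runif(48 * 40 * 56), c(48, 40, 56)))
  for (ov in c(0, 5, 16)) {
    out <- apply_tiled(identity_model(), v, tile_shape = c(24, 24, 24),
                       overlap = ov)
    expect_lt(max(abs(vol_data(out) - vol_data(v))), 1e-6)
  }
  # constant-plus-one model: no seams anywhere
  plus1 <- structure(list(), class = "plus_one_model")
  assign("predict.plus_one_model",
         function(object, volume, ...) vol_data(volume) + 1,
         envir = globalenv())
  on.exit(rm("predict.plus_one_model", envir = globalenv()))
  out1 <- apply_tiled(plus1, v, tile_shape = c(24, 24, 24), overlap = 8)
  expect_lt(max(abs(vol_data(out1) - (vol_data(v) + 1))), 1e-6)
})

test_that("blend weights sum to one at every voxel", {
  w <- tile_weight_field(c(64, 64, 64), tile_shape = c(32, 32, 32),
                         overlap = 16)
  expect_lt(max(abs(w - 1)), 1e-12)
  w2 <- tile_weight_field(c(40, 40, 40), tile_shape = c(24, 24, 24),
                          overlap = 8)
  expect_lt(max(abs(w2 - 1)), 1e-12)
})

test_that("tiled application is exact for linear models", {
  m <- train_reference_model(
    list(list(gt = volume3d(array(stats::runif(24^3), rep(24, 3))),
              aberrated = volume3d(array(stats::runif(24^3), rep(24, 3))))),
    epochs = 1, patch_shape = c(24, 24, 24), patches_per_epoch = 2,
    kernel_size = 7, rng_seed = 1)
  # drop the non-negativity clip so the operator is exactly linear
  lin <- structure(list(kernel = m$kernel), class = "linear_filter_model")
  assign("predict.linear_filter_model",
         function(object, volume, ...)
           aberrsim:::conv_kernel(vol_data(volume), object$kernel),
         envir = globalenv())
  on.exit(rm("predict.linear_filter_model", envir = globalenv()))
  v <- volume3d(array(stats::runif(48^3), c(48, 48, 48)))
  whole <- predict(lin, v)
  tiled <- apply_tiled(lin, v, tile_shape = c(48, 48, 48), overlap = 0)
  expect_lt(max(abs(vol_data(tiled) - whole)), 1e-5)
})

test_that("training on identity pairs learns a near-identity operator", {
  v <- blur_with_psf(test_phantom(32, seed = 1,
                                  counts = c(dots = 4, spheres = 1)),
                     psf_from_pupil(test_config(32)))
  m <- train_reference_model(list(list(gt = v, aberrated = v)),
                             epochs = 2, patch_shape = c(32, 32, 32),
                             patches_per_epoch = 2, rng_seed = 3)
  # ridge regularization and kernel truncation leave a small residual;
  # the loss must still collapse to a small fraction of the signal power
  expect_lt(m$loss[length(m$loss)], 0.01 * mean(vol_data(v)^2))
  pred <- predict(m, v)
  relerr <- sqrt(sum((pred - vol_data(v))^2) / sum(vol_data(v)^2))
  expect_lt(relerr, 0.05)
  expect_gt(stats::cor(as.vector(pred), as.vector(vol_data(v))), 0.99)
})

test_that("training is deterministic given the seed", {
  s <- lapply(1:2, function(i) {
    gt <- blur_with_psf(test_phantom(32, seed = 50 + i,
                                     counts = c(dots = 4, spheres = 1)),
                        psf_from_pupil(test_config(32)))
    co <- sample_coefficients(simulation_bounds(mode = "fixed_rms",
                                                amplitude = 1),
                              rng_seed = 60 + i)
    list(gt = gt, aberrated = degrade(gt, test_config(32), co))
  })
  m1 <- train_reference_model(s, epochs = 2, patch_shape = c(32, 32, 32),
                              rng_seed = 11)
  m2 <- train_reference_model(s, epochs = 2, patch_shape = c(32, 32, 32),
                              rng_seed = 11)
  expect_identical(m1$loss, m2$loss)
  expect_identical(m1$kernel, m2$kernel)
  expect_error(train_reference_model(list()), "no training pairs")
})

test_that("a trained model improves aberrated phantoms on held-out pairs", {
  cfg <- test_config(48)
  ipsf <- psf_from_pupil(cfg)
  prof <- simulation_bounds(mode = "fixed_rms", amplitude = 1)
  mk_pair <- function(i) {
    gt <- blur_with_psf(test_phantom(48, seed = 900 + i), ipsf)
    co <- sample_coefficients(prof, rng_seed = 950 + i)
    ab <- add_poisson_noise(degrade(gt, cfg, co), 16, rng_seed = 980 + i)
    ab <- volume3d(vol_data(ab) * mean(gt) / mean(ab))
    list(gt = gt, aberrated = ab)
  }
  train <- lapply(1:8, mk_pair)
  held <- lapply(9:11, mk_pair)
  m <- train_reference_model(train, epochs = 2,
                             patch_shape = c(48, 48, 48),
                             patches_per_epoch = 1, rng_seed = 4)
  gain <- vapply(held, function(p)
    ssim_psnr(volume3d(predict(m, p$aberrated)), p$gt)$ssim -
      ssim_psnr(p$aberrated, p$gt)$ssim, numeric(1))
  expect_gt(mean(gain), 0)
})
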