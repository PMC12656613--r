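# Spectral calibration, moving-average denoising, band selection and the
# 1D-CNN spectral encoder.

make_triplet <- function(wl, s, d, r) {
  structure(list(wavelengths = wl, sample_intensity = s, dark_intensity = d,
                 reference_intensity = r), class = "plum_spectrum")
}

test_that("transmittance implements (S - D) / (R - D)", {
  wl <- seq(400, 1600, length.out = 5)
  expect_equal(compute_transmittance(
    make_triplet(wl, rep(9, 5), rep(0, 5), rep(9, 5)))$transmittance, rep(1, 5))
  expect_equal(compute_transmittance(
    make_triplet(wl, rep(2, 5), rep(2, 5), rep(9, 5)))$transmittance, rep(0, 5))
  expect_equal(compute_transmittance(
    make_triplet(wl, rep(5, 5), rep(1, 5), rep(9, 5)))$transmittance, rep(0.5, 5))

  err <- tryCatch(compute_transmittance(
    make_triplet(wl, rep(5, 5), c(1, 9, 1, 1, 1), rep(9, 5))),
    plum_calibration_error = identity)
  expect_s3_class(err, "plum_calibration_error")
  expect_match(conditionMessage(err), "700")  # offending wavelength named

  # invariance to a common positive gain on S, D, R
  s <- runif(5, 4, 8); d <- runif(5, 0, 1); r <- runif(5, 9, 12)
  t1 <- compute_transmittance(make_triplet(wl, s, d, r))$transmittance
  t2 <- compute_transmittance(make_triplet(wl, 3.7 * s, 3.7 * d, 3.7 * r))$transmittance
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("moving average shrinks at edges and bounds the range", {
  expect_equal(moving_average(c(1, 2, 3, 4, 5), 3), c(1.5, 2, 3, 4, 4.5))
  expect_equal(moving_average(c(1, 2, 3, 4, 5), 1), c(1, 2, 3, 4, 5))
  expect_equal(moving_average(rep(2.5, 9), 5), rep(2.5, 9))
  expect_error(moving_average(1:10, 4), class = "plum_parameter_error")
  expect_error(moving_average(1:10, 11), class = "plum_parameter_error")

  set.seed(31)
  for (k in 1:20) {
    x <- rnorm(50)
    y <- moving_average(x, sample(c(3, 5, 7, 9), 1))
    expect_lte(max(y), max(x) + 1e-12)
    expect_gte(min(y), min(x) - 1e-12)
  }
})

test_that("band selection keeps exactly the grid points inside the bands", {
  cfg <- synthetic_config(noise_sd = 0)
  tr <- compute_transmittance(simulate_raw_spectrum(9, "semi_ripe", "consistent", cfg))
  full <- select_bands(tr, band_selection(list(c(350, 1700))))
  expect_equal(full$values, tr$transmittance)

  sel <- select_bands(tr, band_selection())
  # analytic count: grid is 350 + i * 1350/511, i = 0..511
  i <- 0:511
  wl <- 350 + i * 1350 / 511
  expected <- sum(wl >= 900 & wl <= 1350) + sum(wl >= 1400 & wl <= 1600)
  expect_equal(length(sel$values), expected)

  a <- select_bands(tr, band_selection(list(c(900, 1350))))
  b <- select_bands(tr, band_selection(list(c(1400, 1600))))
  expect_equal(length(sel$values), length(a$values) + length(b$values))

  expect_error(band_selection(list(c(900, 1350), c(1300, 1600))),
               class = "plum_band_error")
  expect_error(select_bands(tr, band_selection(list(c(2000, 2100)))),
               class = "plum_band_error")

  # fixed composition order: transmittance -> smoothing -> band selection
  manual <- select_bands(moving_average(compute_transmittance(
    simulate_raw_spectrum(9, "semi_ripe", "consistent", cfg)), 5), band_selection())
  piped <- preprocess_spectrum(simulate_raw_spectrum(9, "semi_ripe", "consistent", cfg))
  expect_identical(piped, manual)
})

test_that("spectral encoder emits 512 features deterministically", {
  enc <- spectral_encoder(246, out_dim = 512, seed = 5)
  x <- runif(246)
  g <- encode_spectrum(x, enc)
  expect_equal(dim(g), c(1L, 512L))
  expect_identical(encode_spectrum(x, enc), g)

  X <- matrix(runif(8 * 246), 8)
  G <- encode_spectrum(X, enc)
  expect_equal(dim(G), c(8L, 512L))
  # per-sample outputs are independent of batch composition
  expect_equal(G[3, ], as.vector(encode_spectrum(X[3, ], enc)), tolerance = 1e-12)

  expect_error(encode_spectrum(runif(100), enc), class = "plum_shape_error")

  cal <- calibrate_spectral_encoder(enc, X)
  G2 <- encode_spectrum(X, cal)
  expect_equal(G2[5, ], as.vector(encode_spectrum(X[5, ], cal)), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(G, G2)))  # calibration changes the map
})

test_that("spectral features recover SSC after pre-training", {
  cfg <- synthetic_config(n_samples = 80, seed = 17)
  ds <- generate_dataset(cfg, render_images = FALSE)
  band <- t(vapply(ds$samples,
                   function(s) preprocess_spectrum(s$spectrum)$values,
                   numeric(246)))
  enc <- spectral_encoder(246, out_dim = 32, width_factor = 0.25, seed = 3)
  enc <- calibrate_spectral_encoder(enc, band[1:60, ])
  conv <- spectral_conv_features(enc, band)
  enc <- pretrain_encoder(enc, conv[1:60, ], ds$metadata$ssc_brix[1:60],
                          conv[61:80, ], ds$metadata$ssc_brix[61:80],
                          epochs = 30, seed = 4)
  f <- plumgrade:::fc_forward(enc$fc, conv)
  fit <- stats::lm.fit(cbind(1, f[1:60, ]), ds$metadata$ssc_brix[1:60])
  pred <- cbind(1, f[61:80, ]) %*% fit$coefficients
  expect_gt(stats::cor(pred, ds$metadata$ssc_brix[61:80]), 0.9)
})
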