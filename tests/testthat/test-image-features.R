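# Segmentation, standardization, manual descriptors (red ratio,
# circularity, Hough cross-check) and the convolutional image encoder.

test_that("fixed-threshold segmentation recovers the ground-truth mask", {
  r <- render_plum_image(0.4, 0.85, synthetic_config(image_size = 160), seed = 8)
  seg <- segment_plum(r$image)
  jac <- sum(seg$mask & r$mask) / sum(seg$mask | r$mask)
  expect_gte(jac, 0.98)
  # crop is aligned with the mask bounding box and background is zeroed
  expect_equal(dim(seg$cropped)[1:2], dim(seg$cropped_mask))
  expect_true(all(seg$cropped[, , 1][!seg$cropped_mask] == 0))

  expect_error(segment_plum(array(0, c(32, 32, 3))),
               class = "plum_segmentation_error")

  full <- segment_plum(array(0.5, c(32, 32, 3)), threshold = 0)
  expect_true(all(full$mask))
})

test_that("standardization yields 224 x 224 with values preserved", {
  r <- render_plum_image(0.4, 0.85, synthetic_config(image_size = 160), seed = 8)
  std <- standardize_image(segment_plum(r$image)$cropped)
  expect_equal(dim(std), c(224, 224, 3))
  expect_true(all(std >= 0 & std <= 1))

  const <- standardize_image(array(rep(c(0.2, 0.5, 0.7), each = 50 * 60),
                                   c(50, 60, 3)))
  expect_equal(unique(as.vector(const[, , 1])), 0.2, tolerance = 1e-6)
  expect_equal(unique(as.vector(const[, , 3])), 0.7, tolerance = 1e-6)

  already <- array(runif(224 * 224 * 3), c(224, 224, 3))
  expect_equal(standardize_image(already), already, tolerance = 1e-6)
})

test_that("red ratio matches the rendered ground truth and is rotation-invariant", {
  cfg <- synthetic_config(image_size = 160)
  half <- render_plum_image(0.5, 0.9, cfg, seed = 12)
  expect_lt(abs(red_ratio(half$image, half$mask) - 0.5), 0.03)

  green <- array(rep(c(0, 0.8, 0), each = 40 * 40), c(40, 40, 3))
  expect_equal(red_ratio(green, matrix(TRUE, 40, 40)), 0)
  expect_error(red_ratio(green, matrix(FALSE, 40, 40)),
               class = "plum_domain_error")

  rot90 <- function(img) aperm(img[rev(seq_len(dim(img)[1])), , , drop = FALSE],
                               c(2, 1, 3))
  r0 <- red_ratio(half$image, half$mask)
  img <- half$image; msk <- half$mask
  for (k in 1:3) {
    img <- rot90(img)
    msk <- t(msk[rev(seq_len(nrow(msk))), ])
    expect_lt(abs(red_ratio(img, msk) - r0), 0.01)
  }
})

test_that("circularity follows 4*pi*A/p^2 with rasterization accuracy", {
  expect_equal(circularity_from_measures(1^2, 4 * 1), pi / 4, tolerance = 1e-12)

  d <- circularity(disk_mask(80))
  expect_gte(d$circularity, 0.95)
  expect_lte(d$circularity, 1.05)
  # stored area/perimeter reproduce the reported value exactly
  expect_equal(d$circularity, 4 * pi * d$area / d$perimeter^2, tolerance = 1e-9)
  # area oracle: independent pixel count of the filled mask
  expect_equal(d$area, sum(disk_mask(80)))

  # scale invariance up to discretization
  expect_lt(abs(circularity(disk_mask(40))$circularity - d$circularity), 0.03)

  line <- matrix(FALSE, 64, 64); line[32, 5:60] <- TRUE
  expect_error(circularity(line), class = "plum_filter_error")
  expect_error(circularity(matrix(FALSE, 8, 8)), class = "plum_domain_error")
})

test_that("Hough cross-check agrees on disks and degrades with eccentricity", {
  dm <- disk_mask(60)
  cd <- circularity(dm)
  agree_disk <- hough_cross_check(dm, cd)
  expect_gte(agree_disk, 0.9)

  ell <- render_plum_image(0.5, 0.3, synthetic_config(image_size = 200), seed = 3)
  ce <- circularity(ell$mask)
  expect_lt(hough_cross_check(ell$mask, ce), agree_disk)

  blank <- cd; blank$contour <- cd$contour[1:4, ]
  expect_equal(hough_cross_check(dm, blank), 0)
})

test_that("image encoder has the contracted shape and determinism", {
  enc <- image_encoder(out_dim = 128, base_width = 2, input_size = 64, seed = 2)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  f <- encode_image(img, enc)
  expect_equal(dim(f), c(1L, 128L))
  expect_identical(encode_image(img, enc), f)

  expect_error(encode_image(array(0.1, c(32, 32, 3)), enc),
               class = "plum_shape_error")

  # segmentation zeroes the background, so images differing only outside the
  # fruit encode identically
  r <- render_plum_image(0.6, 0.9, synthetic_config(image_size = 96), seed = 4)
  other <- r$image
  for (ch in 1:3) {
    plane <- other[, , ch]
    plane[!r$mask] <- runif(sum(!r$mask), 0, 0.08)
    other[, , ch] <- plane
  }
  std1 <- standardize_image(segment_plum(r$image)$cropped, 64)
  std2 <- standardize_image(segment_plum(other)$cropped, 64)
  expect_equal(encode_image(std1, enc), encode_image(std2, enc),
               tolerance = 1e-12)
})

test_that("encoder pre-training makes features predictive of its targets", {
  ds <- meta_dataset(n = 100, seed = 101,
                     class_proportions = c(0.10, 0.50, 0.40), image_size = 96)
  enc <- image_encoder(out_dim = 32, base_width = 4, input_size = 96, seed = 6)
  imgs <- lapply(seq_len(100), function(i) {
    standardize_image(segment_plum(dataset_image(ds, i))$cropped, 96)
  })
  conv <- image_conv_features(enc, imgs)
  tr <- 1:75; va <- 76:100
  targets <- cbind(ds$metadata$red_fraction, ds$metadata$circularity)
  enc2 <- pretrain_encoder(enc, conv[tr, ], targets[tr, ], conv[va, ],
                           targets[va, ], epochs = 150, batch_size = 16,
                           patience = 25, seed = 7)
  f <- encode_image(conv, enc2, conv_features = TRUE)
  # held-out red fraction is linearly recoverable from the learned features
  fit <- stats::lm.fit(cbind(1, f[tr, ]), targets[tr, 1])
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  pred <- cbind(1, f[va, ]) %*% beta
  expect_gt(stats::cor(pred, targets[va, 1]), 0.9)
})
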