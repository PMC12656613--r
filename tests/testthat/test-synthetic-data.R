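# Synthetic plum generator: SSC sampler, image renderer, spectral simulator,
# and the full dataset contract.

test_that("SSC sampler recovers class means and spreads", {
  cfg <- synthetic_config()
  x <- sample_ssc("ripe", cfg, n = 10000, seed = 1)
  se <- cfg$ssc_sds[["ripe"]] / sqrt(10000)
  expect_lt(abs(mean(x) - 10.57), 3 * se)

  u <- sample_ssc("unripe", cfg, n = 10000, seed = 2)
  expect_lt(abs(stats::sd(u) - cfg$ssc_sds[["unripe"]]), 0.05)
  expect_true(all(u > 0 & u < 30))

  degenerate <- synthetic_config(ssc_sds = c(0, 0, 0))
  expect_equal(sample_ssc("semi_ripe", degenerate, n = 50, seed = 3),
               rep(8.66, 50))

  expect_error(sample_ssc("overripe", cfg), class = "plum_enum_error")
})

test_that("renderer controls red fraction and shape exactly", {
  cfg <- synthetic_config(image_size = 160)
  full <- render_plum_image(1, 0.9, cfg, seed = 4)
  expect_equal(sum(full$red_mask), sum(full$mask))
  expect_equal(red_ratio(full$image, full$mask), 1)

  circle <- render_plum_image(0.3, 1, cfg, seed = 5)
  expect_lt(abs(circle$circularity - 1), 0.05)

  half <- render_plum_image(0.5, 0.8, cfg, seed = 6)
  expect_lt(abs(sum(half$red_mask) / sum(half$mask) - 0.5), 0.02)
  expect_true(all(half$image >= 0 & half$image <= 1))
  # background stays dark enough for fixed-threshold segmentation
  bg <- plumgrade:::rgb_to_gray(half$image)[!half$mask]
  expect_lt(max(bg), 0.1)
})

test_that("simulated spectra carry absorption valleys and maturity gain", {
  cfg0 <- synthetic_config(noise_sd = 0)
  a <- simulate_raw_spectrum(9, "semi_ripe", "consistent", cfg0, seed = 7)
  b <- simulate_raw_spectrum(9, "semi_ripe", "consistent", cfg0, seed = 99)
  expect_identical(a, b)  # noise-free spectra are seed-independent

  expect_true(all(a$reference_intensity > a$dark_intensity))
  expect_true(all(diff(a$wavelengths) > 0))

  tr <- compute_transmittance(a)
  at <- function(w) tr$transmittance[which.min(abs(tr$wavelengths - w))]
  expect_lt(at(980), at(1050))
  expect_lt(at(1190), at(1100))
  expect_lt(at(1450), at(1550))

  band_mean <- function(ssc, cls) {
    t <- compute_transmittance(simulate_raw_spectrum(ssc, cls, "consistent", cfg0))
    mean(t$transmittance[t$wavelengths >= 900 & t$wavelengths <= 1350])
  }
  m <- c(band_mean(5.95, "unripe"), band_mean(8.66, "semi_ripe"),
         band_mean(10.57, "ripe"))
  expect_true(all(diff(m) > 0))

  # negative archetypes keep SSC in the valleys but shift the broadband gain
  neg1 <- compute_transmittance(simulate_raw_spectrum(5.5, "unripe", "negative1", cfg0))
  neg2 <- compute_transmittance(simulate_raw_spectrum(5.5, "unripe", "negative2", cfg0))
  ripe <- compute_transmittance(simulate_raw_spectrum(10.6, "ripe", "consistent", cfg0))
  gap <- function(x) mean(abs(x$transmittance - ripe$transmittance))
  expect_lt(gap(neg2), gap(neg1))
})

test_that("generated datasets are reproducible and label-consistent", {
  cfg <- synthetic_config(n_samples = 200, seed = 31)
  d1 <- generate_dataset(cfg, render_images = FALSE, simulate_spectra = FALSE)
  d2 <- generate_dataset(cfg, render_images = FALSE, simulate_spectra = FALSE)
  expect_identical(d1$metadata, d2$metadata)

  # grades always reproducible from the comprehensive-score pipeline
  q <- quality_indicators(d1$metadata$ssc_brix, d1$metadata$red_fraction,
                          d1$metadata$circularity, d1$bounds)
  expect_identical(as.character(q$grade), d1$metadata$grade)
  expect_true(all(pmin(abs(q$score - 0.3), abs(q$score - 0.7)) >=
                    cfg$score_margin - 1e-12))

  expect_error(generate_dataset(synthetic_config(n_samples = 5)),
               class = "plum_size_error")
})

test_that("class proportions track the configured targets", {
  ds <- generate_dataset(
    synthetic_config(n_samples = 780,
                     class_proportions = c(0.0577, 0.50, 0.4423), seed = 11),
    render_images = FALSE, simulate_spectra = FALSE)
  prop <- table(factor(ds$metadata$grade,
                       levels = c("premium", "standard", "processing"))) / 780
  target <- c(45, 390, 345) / 780
  expect_true(all(abs(as.numeric(prop) - target) < 0.05))
})

test_that("lazily rendered images match eagerly rendered ones", {
  cfg <- synthetic_config(n_samples = 12, image_size = 80, seed = 77)
  eager <- generate_dataset(cfg, simulate_spectra = FALSE)
  lazy <- generate_dataset(cfg, render_images = FALSE, simulate_spectra = FALSE)
  for (i in c(1, 7, 12)) {
    expect_identical(dataset_image(lazy, i), eager$samples[[i]]$image)
  }
})

test_that("single modalities stay ambiguous while the triple separates", {
  ds <- meta_dataset(n = 400, seed = 303)
  md <- ds$metadata
  neg <- md[md$archetype != "consistent", ]
  prem <- md[md$grade == "premium", ]
  expect_gt(nrow(neg), 0)
  # negatives share the premium image-indicator distribution but never the grade
  expect_true(all(neg$red_fraction >= min(prem$red_fraction) - 0.02))
  expect_true(all(neg$grade != "premium"))
  # spectra-visible information (SSC + maturity gain) cannot separate
  # negative1 (standard) from consistent processing fruit
  n1 <- md[md$archetype == "negative1", ]
  proc <- md[md$grade == "processing" & md$archetype == "consistent", ]
  overlap <- vapply(n1$ssc_brix, function(s) any(abs(proc$ssc_brix - s) < 0.2),
                    logical(1))
  expect_gt(mean(overlap), 0.5)
  expect_true(all(n1$grade == "standard"))
})

test_that("datasets round-trip through disk", {
  ds <- generate_dataset(synthetic_config(n_samples = 10, image_size = 64,
                                          seed = 55))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$metadata$grade, ds$metadata$grade)
  expect_equal(back$samples[[3]]$spectrum$sample_intensity,
               ds$samples[[3]]$spectrum$sample_intensity, tolerance = 1e-6)
  # PNG quantizes to 8 bits per channel
  expect_lt(max(abs(back$samples[[5]]$image - ds$samples[[5]]$image)), 1 / 255)
})
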