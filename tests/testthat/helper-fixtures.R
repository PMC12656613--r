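# Shared small fixtures, built in code and memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# 60-sample dataset with small images, spectra included; premium is
# over-represented so every split keeps a few premium samples.
tiny_dataset <- function() {
  memo("tiny_dataset", generate_dataset(
    synthetic_config(n_samples = 60, image_size = 96, seed = 101,
                     class_proportions = c(0.10, 0.50, 0.40))))
}

# metadata-only dataset for distributional checks
meta_dataset <- function(n = 300, seed = 202, ...) {
  generate_dataset(synthetic_config(n_samples = n, seed = seed, ...),
                   render_images = FALSE, simulate_spectra = FALSE)
}

# a rasterized disk mask
disk_mask <- function(r = 80, pad = 20) {
  n <- 2 * (r + pad)
  yy <- row(matrix(0, n, n)); xx <- col(matrix(0, n, n))
  (yy - n / 2)^2 + (xx - n / 2)^2 <= r^2
}

# small fusion config for fast head training
tiny_fusion_config <- function(...) {
  fusion_config(image_dim = 8L, spectral_dim = 4L, hidden_widths = c(16L, 8L),
                dropout_rate = 0.1, batch_size = 16L, max_epochs = 60L,
                patience = 15L, seed = 11L, ...)
}

# Linearly-encoded toy features for head training: three grade clusters.
toy_grade_features <- function(n_per = 20, d = 12, seed = 5) {
  with_seed(seed, {
    centers <- list(processing = -2, standard = 0, premium = 2)
    X <- do.call(rbind, lapply(centers, function(mu)
      matrix(stats::rnorm(n_per * d, mu, 0.4), n_per, d)))
    y <- rep(names(centers), each = n_per)
    ord <- sample(length(y))
    list(X = X[ord, ], y = y[ord])
  })
}
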