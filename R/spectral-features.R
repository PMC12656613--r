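# Spectral calibration, denoising, absorption-band selection and the 1D-CNN
# spectral encoder.

#' Compute transmittance from a raw spectral triplet
#'
#' Elementwise `(S - D) / (R - D)` where S is the sample intensity, D the
#' dark current and R the white-reference intensity.
#'
#' @param triplet A `plum_spectrum` (fields `wavelengths`,
#'   `sample_intensity`, `dark_intensity`, `reference_intensity`).
#' @return A `plum_transmittance` list: `wavelengths`, `transmittance`,
#'   `smoothing_window` (1 until smoothed), `bands_applied`.
#' @export
compute_transmittance <- function(triplet) {
  s <- triplet$sample_intensity
  d <- triplet$dark_intensity
  r <- triplet$reference_intensity
  if (length(s) != length(d) || length(s) != length(r))
    stop_plum("plum_calibration_error", "triplet vectors must have equal length")
  eps <- 1e-9 * max(abs(r))
  bad <- which(abs(r - d) <= eps)
  if (length(bad))
    stop_plum("plum_calibration_error",
              "reference does not exceed dark current at wavelengths: %s nm",
              paste(round(triplet$wavelengths[bad], 1), collapse = ", "))
  structure(list(wavelengths = triplet$wavelengths,
                 transmittance = (s - d) / (r - d),
                 smoothing_window = 1L,
                 bands_applied = list()),
            class = "plum_transmittance")
}

#' Centered moving-average denoising
#'
#' Centered moving mean with the window shrinking symmetrically at the
#' edges; `window = 1` is the identity.
#'
#' @param spectrum A `plum_transmittance`, or a bare numeric vector.
#' @param window Odd positive integer, at most the spectrum length.
#' @return Same type as the input, smoothed.
#' @export
moving_average <- function(spectrum, window = 5L) {
  x <- if (inherits(spectrum, "plum_transmittance")) spectrum$transmittance else spectrum
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L || window > n)
    stop_plum("plum_parameter_error",
              "window must be an odd integer between 1 and the spectrum length (%d)", n)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  idx <- seq_len(n)
  # the window truncates at the edges (mean over the available points)
  lo <- pmax(1L, idx - half)
  hi <- pmin(n, idx + half)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  if (inherits(spectrum, "plum_transmittance")) {
    spectrum$transmittance <- out
    spectrum$smoothing_window <- window
    spectrum
  } else {
    out
  }
}

#' Absorption-band selection
#'
#' @param intervals List of `c(low, high)` nm pairs; defaults to the O-H and
#'   C-H characteristic bands 900-1350 nm and 1400-1600 nm.
#' @return An object of class `plum_bands`.
#' @export
band_selection <- function(intervals = list(c(900, 1350), c(1400, 1600))) {
  lows <- vapply(intervals, `[`, numeric(1), 1)
  highs <- vapply(intervals, `[`, numeric(1), 2)
  if (any(highs <= lows)) stop_plum("plum_band_error", "band intervals must be ordered")
  o <- order(lows)
  if (any(lows[o][-1] <= highs[o][-length(o)]))
    stop_plum("plum_band_error", "band intervals must not overlap")
  structure(list(intervals = intervals[o]), class = "plum_bands")
}

#' Restrict a spectrum to selected bands
#'
#' Concatenates the values at grid wavelengths inside any closed interval,
#' preserving wavelength order. Membership is decided by grid points, not
#' interpolation.
#'
#' @param spectrum A `plum_transmittance`.
#' @param bands A [band_selection()].
#' @return List with `wavelengths` and `values` restricted to the bands.
#' @export
select_bands <- function(spectrum, bands = band_selection()) {
  wl <- spectrum$wavelengths
  keep <- rep(FALSE, length(wl))
  for (iv in bands$intervals) keep <- keep | (wl >= iv[1] & wl <= iv[2])
  if (!any(keep)) stop_plum("plum_band_error", "band selection is empty on this grid")
  list(wavelengths = wl[keep], values = spectrum$transmittance[keep])
}

#' Full spectral preprocessing pipeline
#'
#' Fixed composition order: transmittance, moving average, band selection.
#'
#' @param triplet A raw `plum_spectrum`.
#' @param window Moving-average window (default 5).
#' @param bands A [band_selection()].
#' @return Band-restricted spectral vector (with wavelengths).
#' @export
preprocess_spectrum <- function(triplet, window = 5L, bands = band_selection()) {
  tr <- compute_transmittance(triplet)
  tr <- moving_average(tr, window)
  tr$bands_applied <- bands$intervals
  select_bands(tr, bands)
}

#' Build the 1D-CNN spectral encoder
#'
#' Three convolution blocks (kernel sizes 7/5/3, channels 16/32/64 scaled by
#' `width_factor`), each followed by batch normalization, ReLU and
#' max-pooling with stride 2, then a flatten and a linear projection to the
#' feature dimension (no classification layers). Convolution weights are
#' seeded He-initialized fixed projections; batch-norm statistics can be
#' calibrated on a reference batch with [calibrate_spectral_encoder()]; the
#' projection (and feature stage) is trainable via [pretrain_encoder()].
#'
#' @param input_len Length of the band-selected input vector.
#' @param out_dim Feature dimension (default 512).
#' @param width_factor Channel width multiplier (default 1).
#' @param seed Seed for weight initialization.
#' @return A `plum_spectral_encoder`.
#' @export
spectral_encoder <- function(input_len, out_dim = 512L, width_factor = 1,
                             seed = 1L) {
  kernels <- c(7L, 5L, 3L)
  channels <- pmax(1L, as.integer(round(c(16, 32, 64) * width_factor)))
  layers <- list()
  len <- as.integer(input_len)
  cin <- 1L
  with_seed(seed, {
    for (k in seq_along(kernels)) {
      fan_in <- kernels[k] * cin
      layers[[k]] <- list(
        W = matrix(stats::rnorm(channels[k] * fan_in, 0, sqrt(2 / fan_in)),
                   nrow = fan_in, ncol = channels[k]),
        b = rep(0, channels[k]),
        kernel = kernels[k],
        bn_mean = rep(0, channels[k]), bn_var = rep(1, channels[k]),
        bn_gamma = rep(1, channels[k]), bn_beta = rep(0, channels[k])
      )
      cin <- channels[k]
      len <- len %/% 2L
    }
  })
  flat_dim <- len * cin
  fc <- with_seed(seed + 1L, list(
    W = matrix(stats::rnorm(flat_dim * out_dim, 0, sqrt(2 / flat_dim)),
               nrow = flat_dim, ncol = out_dim),
    b = rep(0, out_dim)
  ))
  structure(list(layers = layers, fc = list(fc), input_len = as.integer(input_len),
                 out_dim = as.integer(out_dim), flat_dim = flat_dim,
                 kernels = kernels, channels = channels, seed = as.integer(seed)),
            class = "plum_spectral_encoder")
}

# 1D convolution with same padding via an im2col patch matrix.
# x: L x Cin matrix -> returns L x (k*Cin) patches.
conv1d_patches <- function(x, k) {
  L <- nrow(x); cin <- ncol(x)
  half <- (k - 1L) %/% 2L
  xp <- rbind(matrix(0, half, cin), x, matrix(0, k - 1L - half, cin))
  out <- matrix(0, L, k * cin)
  for (o in seq_len(k)) {
    out[, (o - 1L) * cin + seq_len(cin)] <- xp[o:(o + L - 1L), , drop = FALSE]
  }
  out
}

maxpool1d <- function(x) {
  L <- nrow(x) %/% 2L
  pmax(x[2 * seq_len(L) - 1L, , drop = FALSE], x[2 * seq_len(L), , drop = FALSE])
}

# Forward through the fixed conv stack of the spectral encoder.
# Returns flattened conv features; with collect = TRUE also per-block
# pre-BN outputs (for calibration).
spectral_conv_forward <- function(encoder, x, collect = FALSE) {
  h <- matrix(x, ncol = 1)
  pre <- list()
  for (li in seq_along(encoder$layers)) {
    ly <- encoder$layers[[li]]
    z <- conv1d_patches(h, ly$kernel) %*% ly$W
    z <- sweep(z, 2, ly$b, "+")
    if (collect) pre[[li]] <- z
    zn <- sweep(sweep(z, 2, ly$bn_mean, "-"), 2, sqrt(ly$bn_var + 1e-5), "/")
    zn <- sweep(sweep(zn, 2, ly$bn_gamma, "*"), 2, ly$bn_beta, "+")
    h <- maxpool1d(pmax(zn, 0))
  }
  if (collect) list(flat = as.vector(h), pre = pre) else as.vector(h)
}

#' Calibrate batch-norm statistics of a spectral encoder
#'
#' Sets each block's batch-norm running mean/variance from the convolution
#' outputs over a reference batch (statistics pooled over samples and
#' positions per channel). After calibration the encoder is a fixed
#' deterministic map, independent of batch composition.
#'
#' @param encoder A `plum_spectral_encoder`.
#' @param X Matrix of band vectors (rows = samples).
#' @return The calibrated encoder.
#' @export
calibrate_spectral_encoder <- function(encoder, X) {
  # progressive: calibrate block 1, re-run, calibrate block 2, ...
  for (li in seq_along(encoder$layers)) {
    acc <- NULL
    for (i in seq_len(nrow(X))) {
      z <- spectral_conv_forward(encoder, X[i, ], collect = TRUE)$pre[[li]]
      acc <- rbind(acc, z)
    }
    encoder$layers[[li]]$bn_mean <- colMeans(acc)
    encoder$layers[[li]]$bn_var <- apply(acc, 2, stats::var) * (nrow(acc) - 1) / nrow(acc)
  }
  encoder
}

#' Encode band-selected spectra
#'
#' Runs the fixed convolution blocks and the (optionally pre-trained) linear
#' feature stage; deterministic given the encoder's weights.
#'
#' @param X A band vector, or a matrix with one spectrum per row.
#' @param encoder A [spectral_encoder()].
#' @return Feature matrix (rows = samples) of width `encoder$out_dim`.
#' @export
encode_spectrum <- function(X, encoder) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != encoder$input_len)
    stop_plum("plum_shape_error", "expected input length %d, got %d",
              encoder$input_len, ncol(X))
  flat <- t(vapply(seq_len(nrow(X)),
                   function(i) spectral_conv_forward(encoder, X[i, ]),
                   numeric(encoder$flat_dim)))
  fc_forward(encoder$fc, flat)
}
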