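# Image preprocessing and feature extraction: fixed-threshold grayscale
# segmentation, 224x224 standardization, HSV red-ratio and contour
# circularity descriptors with a Hough-circle cross-check, and the
# VGG16-topology convolutional encoder.

rgb_to_gray <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Segment the plum from a dark background
#'
#' Converts to grayscale (luma weights 0.299/0.587/0.114), thresholds at a
#' fixed normalized level, keeps the largest connected component, fills
#' holes, and crops to the mask bounding box with background pixels zeroed.
#'
#' @param image H x W x 3 array in `[0, 1]`.
#' @param threshold Fixed grayscale threshold (default 0.15; synthetic
#'   backgrounds are darker than this).
#' @return List with `mask` (full-frame logical matrix), `cropped`
#'   (background-zeroed RGB crop), `cropped_mask`, `bbox` and
#'   `threshold_used`.
#' @export
segment_plum <- function(image, threshold = 0.15) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop_plum("plum_shape_error", "expected an H x W x 3 RGB array")
  fg <- rgb_to_gray(image) > threshold
  if (!any(fg))
    stop_plum("plum_segmentation_error",
              "empty foreground at threshold %.3f", threshold)
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  mask <- lab == keep
  mask <- EBImage::fillHull(mask) > 0
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  cropped <- image[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE]
  cmask <- mask[rows[1]:rows[2], cols[1]:cols[2]]
  for (ch in 1:3) cropped[, , ch] <- cropped[, , ch] * cmask
  list(mask = mask, cropped = cropped, cropped_mask = cmask,
       bbox = c(rows[1], rows[2], cols[1], cols[2]), threshold_used = threshold)
}

#' Standardize an image to 224 x 224
#'
#' Bilinear resampling to the fixed input size of the image encoder; values
#' stay within `[0, 1]`. An image already at the target size is returned
#' unchanged.
#'
#' @param image H x W x 3 array.
#' @param size Output side length (default 224).
#' @return `size` x `size` x 3 array.
#' @export
standardize_image <- function(image, size = 224L) {
  if (length(dim(image)) != 3L || any(dim(image)[1:2] < 1L))
    stop_plum("plum_shape_error", "expected a nonempty H x W x 3 array")
  if (all(dim(image)[1:2] == size)) return(image)
  out <- EBImage::resize(EBImage::Image(image, colormode = "Color"),
                         w = size, h = size, filter = "bilinear")
  array(clamp(EBImage::imageData(out), 0, 1), c(size, size, 3))
}

#' Peel red-colour ratio
#'
#' Converts to HSV and counts, within the fruit mask, pixels whose hue falls
#' in the red window with sufficient saturation and value; the ratio is red
#' pixels over mask pixels.
#'
#' @param image H x W x 3 RGB array.
#' @param mask Logical matrix of fruit pixels.
#' @param hsv_thresholds List with `hue_low` (default 20 degrees), `hue_high`
#'   (default 320), `s_min` (0.3), `v_min` (0.2); red hue is
#'   `<= hue_low` or `>= hue_high`.
#' @return Red ratio in `[0, 1]`.
#' @export
red_ratio <- function(image, mask,
                      hsv_thresholds = list(hue_low = 20, hue_high = 320,
                                            s_min = 0.3, v_min = 0.2)) {
  if (!any(mask)) stop_plum("plum_domain_error", "mask is empty")
  px <- which(mask)
  rgb <- rbind(image[, , 1][px], image[, , 2][px], image[, , 3][px])
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  h <- hsv[1, ] * 360; s <- hsv[2, ]; v <- hsv[3, ]
  red <- (h <= hsv_thresholds$hue_low | h >= hsv_thresholds$hue_high) &
    s >= hsv_thresholds$s_min & v >= hsv_thresholds$v_min
  mean(red)
}

#' Circularity from area and perimeter
#'
#' The shape descriptor `C = 4 * pi * A / p^2`: 1 for a perfect disk,
#' smaller for elongated or ragged contours.
#'
#' @param area Enclosed area.
#' @param perimeter Contour perimeter.
#' @return Circularity value.
#' @export
circularity_from_measures <- function(area, perimeter) {
  4 * pi * area / perimeter^2
}

# Perimeter of an 8-connected boundary chain with corner-corrected weights
# (0.980 per axial step, 1.406 per diagonal step, -0.091 per direction
# change). Plain sqrt(2)-weighted chains overestimate smooth perimeters by
# ~5%, which would bias disk circularity down to ~0.9; the corner term
# removes most of that bias.
chain_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 3) return(0)
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  d <- nxt - contour
  diag_step <- d[, 1] != 0 & d[, 2] != 0
  codes <- atan2(d[, 2], d[, 1])
  corners <- sum(codes != c(codes[-1], codes[1]))
  0.980 * sum(!diag_step) + 1.406 * sum(diag_step) - 0.091 * corners
}

#' Contour circularity of a binary mask
#'
#' Extracts external contours of the mask's connected components, computes
#' the enclosed area (filled pixel count) and the corner-corrected
#' chain-code perimeter, and returns `4 * pi * A / p^2` for the largest
#' component passing the dual-threshold contour filter (minimum area
#' fraction of the frame and a plausible circularity range).
#'
#' @param mask Logical matrix.
#' @param filters List with `min_area_frac` (default 0.01 of the frame) and
#'   `c_range` (default `c(0.2, 1.2)`).
#' @return A `plum_circularity` list: `circularity`, `area`, `perimeter`,
#'   `contour` (ordered point matrix), `hough_agreement` (`NA` until
#'   [hough_cross_check()] is run).
#' @export
circularity <- function(mask, filters = list(min_area_frac = 0.01,
                                             c_range = c(0.2, 1.2))) {
  if (!any(mask)) stop_plum("plum_domain_error", "mask is empty")
  lab <- EBImage::bwlabel(mask)
  nobj <- max(lab)
  filled <- EBImage::fillHull(lab)
  contours <- EBImage::ocontour(lab)
  areas <- tabulate(filled[filled > 0], nbins = nobj)
  ord <- order(areas, decreasing = TRUE)
  rejected <- character(0)
  min_area <- filters$min_area_frac * length(mask)
  for (k in ord) {
    contour <- contours[[k]] + 1L  # ocontour is 0-based
    p <- chain_perimeter(contour)
    a <- areas[k]
    cc <- if (p > 0) circularity_from_measures(a, p) else Inf
    if (a >= min_area && cc >= filters$c_range[1] && cc <= filters$c_range[2]) {
      return(structure(list(circularity = cc, area = a, perimeter = p,
                            contour = contour, hough_agreement = NA_real_),
                       class = "plum_circularity"))
    }
    rejected <- c(rejected,
                  sprintf("component %d (area %d, C %.3f)", k, a, cc))
  }
  stop_plum("plum_filter_error",
            "no contour passed the dual-threshold filter; rejected: %s",
            paste(rejected, collapse = "; "))
}

#' Hough-circle cross-check of a contour circularity result
#'
#' Runs a restricted circular Hough transform (centre and radius grids
#' around the contour's centroid and equivalent radius, scored by the
#' fraction of contour points near the candidate circle) and returns the
#' intersection-over-union of the best-scoring disk with the filled contour
#' mask; 0 when no circle is supported.
#'
#' @param mask Logical matrix the contour was extracted from.
#' @param circ A `plum_circularity` result.
#' @return Agreement score in `[0, 1]` (also stored in the returned
#'   attribute-updated result when assigned back).
#' @export
hough_cross_check <- function(mask, circ) {
  pts <- circ$contour
  if (is.null(pts) || nrow(pts) < 8) return(0)
  cy0 <- mean(pts[, 1]); cx0 <- mean(pts[, 2])
  r0 <- sqrt(circ$area / pi)
  radii <- r0 * seq(0.7, 1.3, by = 0.05)
  offs <- seq(-0.2 * r0, 0.2 * r0, length.out = 9)
  best <- list(score = 0)
  for (r in radii) for (dy in offs) for (dx in offs) {
    d <- sqrt((pts[, 1] - (cy0 + dy))^2 + (pts[, 2] - (cx0 + dx))^2)
    score <- mean(abs(d - r) <= 1.5)
    if (score > best$score) best <- list(score = score, r = r, cy = cy0 + dy, cx = cx0 + dx)
  }
  if (best$score < 0.2) return(0)
  h <- nrow(mask); w <- ncol(mask)
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  disk <- (yy - best$cy)^2 + (xx - best$cx)^2 <= best$r^2
  fill <- EBImage::fillHull(mask) > 0
  inter <- sum(disk & fill)
  union <- sum(disk | fill)
  if (union == 0) 0 else inter / union
}

# ---- VGG16-topology image encoder -------------------------------------------

#' Build the VGG16-topology image encoder
#'
#' Five convolution blocks of 2/2/3/3/3 3x3 convolutions (ReLU, then 2x2
#' max-pooling per block) with channel widths `base_width * c(1, 2, 4, 8,
#' 8)`, followed by two fully connected layers of `out_dim` units whose
#' penultimate activation is the feature vector. Convolution weights are
#' seeded He-initialized fixed projections at desk scale; the fully
#' connected stage is trainable via [pretrain_encoder()]. `base_width = 64`
#' gives the full-width channel plan; the default is width-reduced.
#'
#' @param out_dim Feature dimension (default 4096).
#' @param base_width First-block channel count (default 4).
#' @param input_size Input side length (default 224; must be divisible
#'   by 32).
#' @param seed Seed for weight initialization.
#' @return A `plum_image_encoder`.
#' @export
image_encoder <- function(out_dim = 4096L, base_width = 4L, input_size = 224L,
                          seed = 1L) {
  if (input_size %% 32L != 0L)
    stop_plum("plum_config_error", "input_size must be divisible by 32")
  plan <- rep(base_width * c(1L, 2L, 4L, 8L, 8L), times = c(2L, 2L, 3L, 3L, 3L))
  block_of <- rep(1:5, times = c(2L, 2L, 3L, 3L, 3L))
  layers <- list()
  cin <- 3L
  with_seed(seed, {
    for (li in seq_along(plan)) {
      fan_in <- 9L * cin
      layers[[li]] <- list(
        W = matrix(stats::rnorm(fan_in * plan[li], 0, sqrt(2 / fan_in)),
                   nrow = fan_in, ncol = plan[li]),
        b = rep(0, plan[li]),
        pool_after = li == max(which(block_of == block_of[li])))
      cin <- plan[li]
    }
  })
  flat_dim <- (input_size %/% 32L)^2 * plan[length(plan)]
  structure(list(layers = layers, fc = fc_init(c(flat_dim, out_dim, out_dim), seed + 1L),
                 input_size = as.integer(input_size), out_dim = as.integer(out_dim),
                 flat_dim = as.integer(flat_dim), base_width = as.integer(base_width),
                 seed = as.integer(seed)),
            class = "plum_image_encoder")
}

maxpool2d <- function(x) {
  h <- dim(x)[1] %/% 2L; w <- dim(x)[2] %/% 2L
  i1 <- 2L * seq_len(h) - 1L; j1 <- 2L * seq_len(w) - 1L
  v <- pmax.int(x[i1, j1, , drop = FALSE], x[i1 + 1L, j1, , drop = FALSE],
                x[i1, j1 + 1L, , drop = FALSE], x[i1 + 1L, j1 + 1L, , drop = FALSE])
  array(v, c(h, w, dim(x)[3]))
}

# 3x3 same-padding convolution of an H x W x Cin array, computed as nine
# shifted-view matrix products against the row blocks of W (9*Cin x Cout).
conv2d <- function(x, W, b) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]
  h2 <- h + 2L
  xp <- matrix(0, h2 * (w + 2L), cin)
  xp[as.vector(outer(2:(h + 1L), seq_len(w) * h2, "+")), ] <- x
  idx0 <- as.vector(outer(seq_len(h), (seq_len(w) - 1L) * h2, "+"))
  z <- matrix(b, h * w, length(b), byrow = TRUE)
  o <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    z <- z + xp[idx0 + dy + dx * h2, , drop = FALSE] %*%
      W[o * cin + seq_len(cin), , drop = FALSE]
    o <- o + 1L
  }
  z
}

# Forward through the fixed convolution stack; returns the flattened
# final feature map.
image_conv_forward <- function(encoder, img) {
  if (!all(dim(img) == c(encoder$input_size, encoder$input_size, 3L)))
    stop_plum("plum_shape_error", "expected a %d x %d x 3 input",
              encoder$input_size, encoder$input_size)
  h <- img
  for (ly in encoder$layers) {
    z <- conv2d(h, ly$W, ly$b)
    z[z < 0] <- 0
    h <- array(z, c(dim(h)[1], dim(h)[2], ncol(ly$W)))
    if (ly$pool_after) h <- maxpool2d(h)
  }
  as.vector(h)
}

#' Convolutional feature maps for a batch of images
#'
#' Runs the fixed convolution stack of an encoder over a list of
#' standardized images, returning the flattened feature matrix that feeds
#' the trainable fully connected stage.
#'
#' @param encoder A [image_encoder()].
#' @param images A single image array or a list of `input_size` square RGB
#'   arrays.
#' @return Matrix, one row per image, `encoder$flat_dim` columns.
#' @export
image_conv_features <- function(encoder, images) {
  if (!is.list(images)) images <- list(images)
  t(vapply(images, function(im) image_conv_forward(encoder, im),
           numeric(encoder$flat_dim)))
}

#' Encode images into feature vectors
#'
#' Fixed convolution stack followed by the (optionally pre-trained) fully
#' connected stage; deterministic given the encoder's weights.
#'
#' @param images A single standardized image or list thereof, or a
#'   precomputed conv-feature matrix (`conv_features = TRUE`).
#' @param encoder A [image_encoder()].
#' @param conv_features Set `TRUE` when `images` is already the output of
#'   [image_conv_features()].
#' @return Feature matrix (rows = images) of width `encoder$out_dim`.
#' @export
encode_image <- function(images, encoder, conv_features = FALSE) {
  flat <- if (conv_features) images else image_conv_features(encoder, images)
  fc_forward(encoder$fc, flat)
}

#' Pre-train an encoder's fully connected stage
#'
#' Trains the trainable stage of an image or spectral encoder with an
#' auxiliary linear readout under MSE loss (AdamW, early stopping on
#' validation MSE), then discards the readout. Typical targets: measured
#' red ratio and circularity for the image encoder; SSC for the spectral
#' encoder. Targets are z-scored internally.
#'
#' @param encoder A `plum_image_encoder` or `plum_spectral_encoder`.
#' @param X Flattened conv features ([image_conv_features()] /
#'   [spectral_conv_features()]) of the training samples.
#' @param targets Numeric vector or matrix of auxiliary targets.
#' @param Xval,tval Optional validation features/targets.
#' @param epochs,lr,batch_size,patience Training hyperparameters.
#' @param seed Integer seed.
#' @return The encoder with its fully connected stage replaced by the
#'   trained weights; training history in attribute `"history"`.
#' @export
pretrain_encoder <- function(encoder, X, targets, Xval = NULL, tval = NULL,
                             epochs = 25L, lr = 1e-3, batch_size = 128L,
                             patience = 4L, seed = 1L) {
  if (is.null(dim(targets))) targets <- matrix(targets, ncol = 1)
  mu <- colMeans(targets)
  sd <- apply(targets, 2, stats::sd)
  sd[sd < 1e-9] <- 1
  zt <- sweep(sweep(targets, 2, mu, "-"), 2, sd, "/")
  ztval <- NULL
  if (!is.null(tval)) {
    if (is.null(dim(tval))) tval <- matrix(tval, ncol = 1)
    ztval <- sweep(sweep(tval, 2, mu, "-"), 2, sd, "/")
  }
  fit <- train_fc_mse(encoder$fc, X, zt, Xval, ztval, epochs = epochs, lr = lr,
                      batch_size = batch_size, patience = patience, seed = seed)
  encoder$fc <- fit$fc
  attr(encoder, "history") <- fit$history
  encoder
}

#' Flattened conv features of the spectral encoder
#'
#' @param encoder A [spectral_encoder()].
#' @param X Band-vector matrix (rows = samples).
#' @return Matrix of flattened conv outputs feeding the trainable stage.
#' @export
spectral_conv_features <- function(encoder, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  t(vapply(seq_len(nrow(X)), function(i) spectral_conv_forward(encoder, X[i, ]),
           numeric(encoder$flat_dim)))
}
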