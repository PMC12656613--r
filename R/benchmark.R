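# End-to-end grading protocol on a synthetic dataset: generation, stratified
# splitting, minority augmentation, two-modality feature extraction (with
# encoder pre-training on auxiliary targets), head training for the fusion
# model and both single-modal baselines, and clean-test evaluation.

#' Extract image and spectral features for a dataset
#'
#' Per sample: segment, standardize and run the image encoder; calibrate,
#' preprocess (transmittance, moving average, band selection) and run the
#' spectral encoder. The trainable fully connected stages of both encoders
#' are pre-trained on the training split with MSE auxiliary targets
#' (measured red ratio and circularity for images; SSC for spectra), using
#' the validation split for early stopping.
#'
#' @param dataset A `plum_dataset` with images and spectra.
#' @param train_ids,val_ids Index vectors used for encoder pre-training.
#' @param image_enc A [image_encoder()].
#' @param spectral_enc A [spectral_encoder()] matching the band-vector
#'   length, or `NULL` to build one (`spectral_dim`, `width_factor`).
#' @param spectral_dim,width_factor Spectral encoder shape when built here.
#' @param window Moving-average window (default 5).
#' @param bands A [band_selection()].
#' @param pretrain Logical; pre-train the fully connected stages
#'   (default `TRUE`).
#' @param epochs Pre-training epoch cap.
#' @param seed Integer seed.
#' @return List with `image` and `spectral` feature matrices, `fused`,
#'   `manual` (measured red ratio / circularity per sample), and the
#'   encoders.
#' @export
plum_features <- function(dataset, train_ids, val_ids,
                          image_enc = image_encoder(),
                          spectral_enc = NULL, spectral_dim = 512L,
                          width_factor = 1, window = 5L,
                          bands = band_selection(), pretrain = TRUE,
                          epochs = 25L, seed = 1L) {
  n <- length(dataset$samples)
  conv_img <- matrix(0, n, image_enc$flat_dim)
  red <- numeric(n); circ <- numeric(n)
  band_mat <- NULL
  for (i in seq_len(n)) {
    s <- dataset$samples[[i]]
    img <- dataset_image(dataset, i)
    seg <- segment_plum(img)
    red[i] <- red_ratio(img, seg$mask)
    circ[i] <- circularity(seg$mask)$circularity
    std <- standardize_image(seg$cropped, image_enc$input_size)
    conv_img[i, ] <- image_conv_forward(image_enc, std)
    bv <- preprocess_spectrum(s$spectrum, window, bands)$values
    if (is.null(band_mat)) band_mat <- matrix(0, n, length(bv))
    band_mat[i, ] <- bv
  }
  if (is.null(spectral_enc))
    spectral_enc <- spectral_encoder(ncol(band_mat), out_dim = spectral_dim,
                                     width_factor = width_factor,
                                     seed = derive_seed(seed, 31L))
  spectral_enc <- calibrate_spectral_encoder(spectral_enc,
                                             band_mat[train_ids, , drop = FALSE])
  conv_spec <- spectral_conv_features(spectral_enc, band_mat)
  if (pretrain) {
    image_enc <- pretrain_encoder(
      image_enc, conv_img[train_ids, , drop = FALSE],
      cbind(red, circ)[train_ids, , drop = FALSE],
      conv_img[val_ids, , drop = FALSE], cbind(red, circ)[val_ids, , drop = FALSE],
      epochs = epochs, seed = derive_seed(seed, 41L))
    spectral_enc <- pretrain_encoder(
      spectral_enc, conv_spec[train_ids, , drop = FALSE],
      dataset$metadata$ssc_brix[train_ids],
      conv_spec[val_ids, , drop = FALSE], dataset$metadata$ssc_brix[val_ids],
      epochs = epochs, seed = derive_seed(seed, 43L))
  }
  F_img <- encode_image(conv_img, image_enc, conv_features = TRUE)
  F_spec <- fc_forward(spectral_enc$fc, conv_spec)
  list(image = F_img, spectral = F_spec,
       fused = concat_features(F_img, F_spec),
       conv_image = conv_img, conv_spectral = conv_spec,
       manual = data.frame(red_ratio = red, circularity = circ),
       image_encoder = image_enc, spectral_encoder = spectral_enc)
}

#' Run the multimodal grading benchmark
#'
#' Generates a synthetic dataset, splits it 64/16/20 (stratified), augments
#' the premium minority of the training split to 15%, extracts both feature
#' modalities, trains the fusion grading head and the image-only and
#' spectra-only baselines with identical hyperparameters, and evaluates all
#' three on the untouched test split.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n Dataset size (default 600).
#' @param ambiguity_rate Negative-archetype fraction (default 0.2).
#' @param image_dim,base_width,input_size Image encoder shape (defaults
#'   4096 / 4 / 224).
#' @param spectral_dim,spectral_width Spectral encoder shape (defaults
#'   512 / 1).
#' @param image_size Rendered image side (default 320).
#' @param config A [fusion_config()] for the heads (dimensions are set per
#'   model).
#' @param pretrain_epochs Encoder pre-training epoch cap.
#' @param return_features Include the feature matrices and split in the
#'   result (for follow-up experiments such as [noise_experiment()]).
#' @return List with `accuracy` (named: fusion / image / spectral),
#'   `reports` (per-model `plum_eval_report`), `comparison`, `histories`,
#'   `split`, `metadata`, and optionally `features` and `labels`.
#' @export
plum_benchmark <- function(seed = 7L, n = 600L, ambiguity_rate = 0.2,
                           image_dim = 4096L, base_width = 4L, input_size = 224L,
                           spectral_dim = 512L, spectral_width = 1,
                           image_size = 320L,
                           config = fusion_config(), pretrain_epochs = 25L,
                           return_features = FALSE) {
  scfg <- synthetic_config(n_samples = n, ambiguity_rate = ambiguity_rate,
                           image_size = image_size, seed = seed)
  # images are materialized lazily, one at a time, by the feature loop
  ds <- generate_dataset(scfg, render_images = FALSE)
  split <- split_dataset(ds$metadata$grade,
                         split_spec(seed = derive_seed(seed, 3L)))
  aug <- augment_minority(ds, split$train, 0.15, seed = derive_seed(seed, 5L))
  ds <- aug$dataset
  split$train <- aug$train_ids

  feats <- plum_features(ds, split$train, split$val,
                         image_enc = image_encoder(image_dim, base_width,
                                                   input_size,
                                                   seed = derive_seed(seed, 7L)),
                         spectral_dim = spectral_dim,
                         width_factor = spectral_width,
                         epochs = pretrain_epochs, seed = seed)

  labels <- ds$metadata$grade
  # The fusion model classifies pre-extracted (MSE-pre-trained) features;
  # each single-modal baseline is an end-to-end classifier of its modality:
  # its head learns a feature stage directly from the fixed convolutional
  # maps under the label objective, as a stand-alone VGG16 / 1D-CNN
  # classifier would.
  model_feats <- list(fusion = feats$fused, image = feats$conv_image,
                      spectral = feats$conv_spectral)
  histories <- list()
  reports <- list()
  for (tag in names(model_feats)) {
    X <- model_feats[[tag]]
    cfg <- config
    cfg$image_dim <- ncol(X); cfg$spectral_dim <- 0L
    cfg$seed <- derive_seed(seed, 13L)
    fit <- train_model(build_fusion_head(cfg),
                       X[split$train, , drop = FALSE], labels[split$train],
                       X[split$val, , drop = FALSE], labels[split$val], cfg)
    pred <- predict_grade(fit$model, X[split$test, , drop = FALSE])
    reports[[tag]] <- evaluate_predictions(labels[split$test], pred$grade,
                                           model_tag = tag)
    histories[[tag]] <- fit$history
  }
  out <- list(
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    reports = reports,
    comparison = compare_models(reports),
    histories = histories,
    split = split,
    metadata = ds$metadata
  )
  if (return_features) {
    out$features <- model_feats
    out$labels <- labels
  }
  out
}
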