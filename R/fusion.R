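# Feature-level fusion: concatenation of image and spectral feature vectors,
# information-entropy class weighting, the fully connected grading head
# (4608 -> 512 -> 256 -> 3 with batch norm, ReLU, dropout and linear
# residual projections), AdamW training with early stopping, and stratified
# 5-fold cross-validation.

#' Fusion model configuration
#'
#' @param image_dim,spectral_dim Feature dimensions of the two modalities
#'   (defaults 4096 and 512; one may be 0 for single-modal ablations).
#' @param hidden_widths Hidden layer widths of the grading head
#'   (default `c(512, 256)`).
#' @param n_classes Number of grades (default 3).
#' @param dropout_rate Dropout probability after each hidden block
#'   (default 0.3).
#' @param use_residual Add a linear projection skip across each hidden block
#'   (default `TRUE`).
#' @param alpha Information-entropy weighting strength in `[0, 1]`
#'   (default 0.65).
#' @param learning_rate Initial AdamW learning rate (default 0.001).
#' @param weight_decay Decoupled weight decay (default 1e-4).
#' @param batch_size Mini-batch size (default 32).
#' @param max_epochs Maximum training epochs (default 100).
#' @param patience Early-stopping patience in epochs without validation-loss
#'   improvement (default 10).
#' @param restore_best Return the weights of the best-validation epoch
#'   rather than of the stopping epoch (default `TRUE`).
#' @param folds Cross-validation folds (default 5).
#' @param seed Integer seed.
#' @return An object of class `plum_fusion_config`.
#' @export
fusion_config <- function(image_dim = 4096L, spectral_dim = 512L,
                          hidden_widths = c(512L, 256L), n_classes = 3L,
                          dropout_rate = 0.3, use_residual = TRUE,
                          alpha = 0.65, learning_rate = 0.001,
                          weight_decay = 1e-4, batch_size = 32L,
                          max_epochs = 100L, patience = 10L,
                          restore_best = TRUE, folds = 5L,
                          seed = 1L) {
  if (alpha < 0 || alpha > 1)
    stop_plum("plum_config_error", "alpha must lie in [0, 1]")
  if (any(hidden_widths < 1) || batch_size < 1)
    stop_plum("plum_config_error", "hidden widths and batch size must be positive")
  structure(list(image_dim = as.integer(image_dim),
                 spectral_dim = as.integer(spectral_dim),
                 hidden_widths = as.integer(hidden_widths),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate, use_residual = isTRUE(use_residual),
                 alpha = alpha, learning_rate = learning_rate,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 restore_best = isTRUE(restore_best),
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "plum_fusion_config")
}

#' Concatenate image and spectral feature vectors
#'
#' Image block first, then spectral block; no scaling is applied at this
#' stage. Either block may be empty (`NULL` or length 0) for single-modal
#' ablations.
#'
#' @param image_vec,spectral_vec Numeric vectors, or matrices with one
#'   sample per row.
#' @return A matrix of fused features with attributes `image_dim` and
#'   `spectral_dim`.
#' @export
concat_features <- function(image_vec, spectral_vec = NULL) {
  to_mat <- function(x) if (is.null(x)) NULL else if (is.null(dim(x))) matrix(x, nrow = 1) else x
  iv <- to_mat(image_vec); sv <- to_mat(spectral_vec)
  if (!is.null(iv) && any(!is.finite(iv)))
    stop_plum("plum_data_error", "image features contain non-finite entries")
  if (!is.null(sv) && any(!is.finite(sv)))
    stop_plum("plum_data_error", "spectral features contain non-finite entries")
  if (is.null(iv) && is.null(sv))
    stop_plum("plum_data_error", "at least one modality must be present")
  fused <- if (is.null(iv)) sv else if (is.null(sv) || ncol(sv) == 0L) iv else cbind(iv, sv)
  attr(fused, "image_dim") <- if (is.null(iv)) 0L else ncol(iv)
  attr(fused, "spectral_dim") <- if (is.null(sv)) 0L else ncol(sv)
  fused
}

#' Information-entropy class weights
#'
#' With class frequencies `f_c`, the surprisal profile
#' `u_c = (-log f_c) / mean_j(-log f_j)` is blended with uniform weights:
#' `w_c = (1 - alpha) + alpha * u_c`. Rare classes receive weights above 1,
#' the majority class below 1; `alpha = 0` recovers unweighted loss.
#'
#' @param labels Factor/character grade labels (all classes of the model
#'   must be present).
#' @param alpha Blend strength in `[0, 1]` (default 0.65).
#' @param classes Class order (default the grade levels).
#' @return Named per-class weight vector.
#' @export
entropy_class_weights <- function(labels, alpha = 0.65, classes = PLUM_GRADES) {
  counts <- table(factor(as.character(labels), levels = classes))
  if (any(counts == 0))
    stop_plum("plum_weight_error", "class '%s' absent from labels",
              names(counts)[counts == 0][1])
  f <- as.numeric(counts) / sum(counts)
  u <- (-log(f)) / mean(-log(f))
  stats::setNames((1 - alpha) + alpha * u, classes)
}

#' Build the fully connected grading head
#'
#' Layer widths `(image_dim + spectral_dim) -> hidden ... -> n_classes`;
#' each hidden layer is followed by batch normalization, ReLU and dropout,
#' with an optional linear projection skip bridging the block's input to its
#' output. The final layer emits class scores normalized by softmax.
#'
#' @param config A [fusion_config()].
#' @return A `plum_head` model (untrained).
#' @export
build_fusion_head <- function(config = fusion_config()) {
  d_in <- config$image_dim + config$spectral_dim
  model <- head_init(d_in, config$hidden_widths, config$n_classes,
                     config$use_residual, config$seed)
  model$bn <- lapply(config$hidden_widths, function(w)
    list(mean = rep(0, w), var = rep(1, w)))
  model$config <- config
  model$d_in <- d_in
  model$classes <- PLUM_GRADES[seq_len(config$n_classes)]
  model$trained <- FALSE
  class(model) <- "plum_head"
  model
}

#' Number of trainable parameters of a head
#' @param model A `plum_head`.
#' @return Integer parameter count.
#' @export
head_n_params <- function(model) {
  sum(vapply(rapply(head_params(model), length, how = "unlist"), identity, numeric(1)))
}

#' Train a grading head
#'
#' Mini-batch AdamW on class-weighted cross-entropy, monitoring validation
#' loss each epoch; training stops early when the validation loss has not
#' improved for more than `patience` epochs and the best-validation weights
#' are restored. Batch-norm running statistics are tracked with momentum
#' 0.1. Fully reproducible given `config$seed`.
#'
#' @param model A `plum_head` from [build_fusion_head()].
#' @param X,y Training features (rows = samples) and grade labels.
#' @param Xval,yval Validation features and labels.
#' @param config A [fusion_config()]; defaults to the model's own.
#' @param class_weights Optional per-class loss weights (defaults to
#'   [entropy_class_weights()] of the training labels at `config$alpha`).
#' @return List with the trained `model` and a `history` data frame
#'   (per-epoch train loss, validation loss, validation accuracy, plus the
#'   stop epoch).
#' @export
train_model <- function(model, X, y, Xval, yval, config = model$config,
                        class_weights = NULL) {
  if (nrow(X) == 0L || nrow(Xval) == 0L)
    stop_plum("plum_training_error", "training and validation sets must be nonempty")
  if (ncol(X) != model$d_in)
    stop_plum("plum_shape_error", "expected %d input features, got %d",
              model$d_in, ncol(X))
  y_int <- as.integer(factor(as.character(y), levels = model$classes))
  yval_int <- as.integer(factor(as.character(yval), levels = model$classes))
  if (any(is.na(y_int)) || any(is.na(yval_int)))
    stop_plum("plum_label_error", "labels outside the model's class set")
  w <- class_weights %||% tryCatch(
    entropy_class_weights(y, config$alpha, model$classes),
    plum_weight_error = function(e) rep(1, length(model$classes)))
  w <- as.numeric(w)

  params <- head_params(model)
  state <- adamw_init(params)
  momentum <- 0.1
  n <- nrow(X)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_accuracy = numeric())
  best <- list(loss = Inf, params = params, bn = model$bn, epoch = 0L)

  with_seed(config$seed, {
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample(n)
      nb <- max(1L, floor(n / config$batch_size))
      batches <- split(ord, rep(seq_len(nb), length.out = n))
      losses <- numeric(0)
      for (bi in batches) {
        Xb <- X[bi, , drop = FALSE]
        fwd <- head_forward(model, Xb, training = TRUE, dropout = config$dropout_rate)
        for (i in seq_along(model$bn)) {
          model$bn[[i]]$mean <- (1 - momentum) * model$bn[[i]]$mean +
            momentum * fwd$bn_updates[[i]]$mu
          model$bn[[i]]$var <- (1 - momentum) * model$bn[[i]]$var +
            momentum * fwd$bn_updates[[i]]$va
        }
        losses <- c(losses, weighted_ce(fwd$probs, y_int[bi], w))
        grads <- head_backward(model, fwd, Xb, y_int[bi], w, config$dropout_rate)
        upd <- adamw_step(params, grads, state, config$learning_rate,
                          config$weight_decay)
        params <- upd$params
        state <- upd$state
        model <- head_set_params(model, params)
      }
      tl <- mean(losses)
      if (!is.finite(tl))
        stop_plum("plum_training_error", "loss became non-finite at epoch %d", ep)
      vf <- head_forward(model, Xval, training = FALSE)
      vl <- weighted_ce(vf$probs, yval_int, w)
      va <- mean(max.col(vf$probs) == yval_int)
      history <- rbind(history, data.frame(epoch = ep, train_loss = tl,
                                           val_loss = vl, val_accuracy = va))
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, params = params, bn = model$bn, epoch = ep)
      } else if (ep - best$epoch > config$patience) {
        break
      }
    }
  })
  if (config$restore_best) {
    model <- head_set_params(model, best$params)
    model$bn <- best$bn
  } else {
    model <- head_set_params(model, params)
  }
  model$trained <- TRUE
  list(model = model,
       history = structure(history, stop_epoch = nrow(history),
                           best_epoch = best$epoch, fold = NA_integer_))
}

#' Predict grades from fused features
#'
#' Softmax class probabilities and the argmax grade.
#'
#' @param model A trained `plum_head`.
#' @param features Fused feature vector or matrix (rows = samples).
#' @return List with `grade` (factor) and `probs` (matrix, one row per
#'   sample, columns in the model's class order).
#' @export
predict_grade <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != model$d_in)
    stop_plum("plum_shape_error", "expected %d features, got %d",
              model$d_in, ncol(features))
  fwd <- head_forward(model, features, training = FALSE)
  probs <- fwd$probs
  colnames(probs) <- model$classes
  list(grade = factor(model$classes[max.col(probs)], levels = model$classes),
       probs = probs)
}

#' Stratified k-fold cross-validation of the grading head
#'
#' Partitions the training split into `config$folds` stratified folds; each
#' fold in turn serves as the validation subset (20% at 5 folds) while the
#' remainder (80%) trains a fresh head.
#'
#' @param X,y Training-split features and labels.
#' @param config A [fusion_config()].
#' @return List with `folds` (per-fold index sets and histories),
#'   `val_accuracy` per fold, and `summary` (mean and sd).
#' @export
crossvalidate <- function(X, y, config = fusion_config()) {
  y_chr <- as.character(y)
  classes <- unique(y_chr)
  counts <- table(y_chr)
  if (any(counts < config$folds))
    stop_plum("plum_fold_error",
              "class '%s' has fewer samples than folds",
              names(counts)[which.min(counts)])
  fold_of <- integer(length(y_chr))
  with_seed(config$seed, {
    for (cl in classes) {
      idx <- sample(which(y_chr == cl))
      fold_of[idx] <- rep_len(seq_len(config$folds), length(idx))
    }
  })
  folds <- lapply(seq_len(config$folds), function(k) {
    val_ix <- which(fold_of == k)
    tr_ix <- which(fold_of != k)
    fit <- train_model(build_fusion_head(config),
                       X[tr_ix, , drop = FALSE], y_chr[tr_ix],
                       X[val_ix, , drop = FALSE], y_chr[val_ix], config)
    h <- fit$history
    attr(h, "fold") <- k
    acc <- h$val_accuracy[attr(h, "stop_epoch")]
    list(val_idx = val_ix, history = h, val_accuracy = acc, model = fit$model)
  })
  accs <- vapply(folds, `[[`, numeric(1), "val_accuracy")
  list(folds = folds, val_accuracy = accs,
       summary = c(mean = mean(accs), sd = stats::sd(accs)))
}
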