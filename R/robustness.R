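# Adversarial label-noise protocol: flip a fraction of training labels,
# retrain with identical hyperparameters, compare degradation on a clean
# test set across models, and run the prediction/original-label correlation
# diagnostic.

#' Flip a fraction of training labels
#'
#' Selects `round(fraction * n)` training samples uniformly without
#' replacement and flips each to an "opposite" class: premium and
#' processing swap; standard flips to premium or processing with equal
#' probability. The manifest records the originals.
#'
#' @param labels Grade labels of the training split.
#' @param fraction Flip fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `labels` (flipped vector, same type as input) and
#'   `manifest` (data frame: `index`, `original`, `flipped`).
#' @export
flip_labels <- function(labels, fraction, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop_plum("plum_parameter_error", "fraction must lie in (0, 1)")
  n <- length(labels)
  n_flip <- round(fraction * n)
  if (n_flip == 0)
    stop_plum("plum_parameter_error",
              "fraction %.3f of %d samples yields zero flips", fraction, n)
  lab <- as.character(labels)
  flips <- with_seed(seed, {
    idx <- sample(n, n_flip)
    new <- vapply(lab[idx], function(g) switch(g,
      premium = "processing",
      processing = "premium",
      standard = sample(c("premium", "processing"), 1),
      stop_plum("plum_label_error", "unknown grade '%s'", g)), character(1))
    list(idx = idx, new = unname(new))
  })
  out <- lab
  out[flips$idx] <- flips$new
  list(labels = as_grade(out),
       manifest = data.frame(index = flips$idx, original = lab[flips$idx],
                             flipped = flips$new))
}

# Pearson correlation between integer-coded predictions and original labels;
# zero-variance vectors are flagged and reported as r = 0.
prediction_label_correlation <- function(predicted, original) {
  p <- as.integer(as_grade(predicted))
  o <- as.integer(as_grade(original))
  if (stats::sd(p) < 1e-12 || stats::sd(o) < 1e-12) {
    return(list(r = 0, p_value = NA_real_, undefined = TRUE))
  }
  ct <- stats::cor.test(p, o)
  list(r = unname(ct$estimate), p_value = ct$p.value, undefined = FALSE)
}

#' Label-noise robustness experiment
#'
#' For each model (named feature matrices, e.g. fusion / image / spectral):
#' train on clean labels, retrain on flipped labels with identical
#' hyperparameters and seeds, evaluate both on the clean test set, and
#' correlate the noisy model's predictions on the flipped training samples
#' with those samples' original labels (integer-coded Pearson). The test
#' split is never touched by noise. `fraction = 0` is the control path:
#' noisy metrics equal clean metrics.
#'
#' @param features Named list of feature matrices (all samples x dims), one
#'   per model.
#' @param labels Grade labels for all samples.
#' @param split List with `train`, `val`, `test` index vectors.
#' @param fraction Flip fraction in `[0, 1)`.
#' @param config A [fusion_config()] (dimensions are adapted per model).
#' @param seed Integer seed.
#' @return A `plum_noise_result`: per-model list with `clean_accuracy`,
#'   `noisy_accuracy`, `degradation` (percentage points), `pearson_r`,
#'   `p_value`, plus `flip_manifest` and `fraction`.
#' @export
noise_experiment <- function(features, labels, split, fraction,
                             config = fusion_config(), seed = 1L) {
  stopifnot(is.list(features), !is.null(names(features)))
  lab <- as.character(labels)
  tr <- split$train; va <- split$val; te <- split$test
  if (length(intersect(tr, c(va, te))))
    stop_plum("plum_split_error", "splits overlap")

  flip <- NULL
  noisy_lab <- lab
  if (fraction > 0) {
    flip <- flip_labels(lab[tr], fraction, seed)
    noisy_lab[tr] <- as.character(flip$labels)
  }

  per_model <- lapply(names(features), function(tag) {
    X <- features[[tag]]
    cfg <- config
    cfg$image_dim <- ncol(X); cfg$spectral_dim <- 0L
    cfg$seed <- seed
    fit_eval <- function(y) {
      fit <- tryCatch(
        train_model(build_fusion_head(cfg), X[tr, , drop = FALSE], y[tr],
                    X[va, , drop = FALSE], y[va], cfg),
        error = function(e) stop_plum("plum_experiment_error",
                                      "training failed for model '%s': %s",
                                      tag, conditionMessage(e)))
      pred <- predict_grade(fit$model, X[te, , drop = FALSE])
      list(model = fit$model,
           accuracy = mean(as.character(pred$grade) == lab[te]))
    }
    clean <- fit_eval(lab)
    if (fraction > 0) {
      noisy <- fit_eval(noisy_lab)
      flip_idx <- tr[flip$manifest$index]
      pred_noisy <- predict_grade(noisy$model, X[flip_idx, , drop = FALSE])
      corr <- prediction_label_correlation(pred_noisy$grade, lab[flip_idx])
    } else {
      noisy <- clean
      corr <- list(r = NA_real_, p_value = NA_real_, undefined = NA)
    }
    list(model_tag = tag,
         clean_accuracy = clean$accuracy,
         noisy_accuracy = noisy$accuracy,
         degradation = 100 * (clean$accuracy - noisy$accuracy),
         pearson_r = corr$r, p_value = corr$p_value,
         pearson_undefined = corr$undefined)
  })
  names(per_model) <- names(features)
  structure(list(models = per_model, fraction = fraction,
                 flip_manifest = if (is.null(flip)) NULL else flip$manifest,
                 flipped_ids = if (is.null(flip)) integer(0) else tr[flip$manifest$index]),
            class = "plum_noise_result")
}

#' @export
print.plum_noise_result <- function(x, ...) {
  cat(sprintf("label-noise experiment (fraction %.2f)\n", x$fraction))
  for (m in x$models) {
    cat(sprintf("  %-9s clean %.4f  noisy %.4f  degradation %+.1f pts  r = %s\n",
                m$model_tag, m$clean_accuracy, m$noisy_accuracy, -m$degradation,
                format(m$pearson_r, digits = 3)))
  }
  invisible(x)
}
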