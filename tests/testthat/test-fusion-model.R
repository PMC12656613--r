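# Feature concatenation, entropy class weighting, the grading head, training
# with early stopping, cross-validation and prediction.

test_that("concatenation preserves block order and dimensions", {
  iv <- matrix(runif(2 * 4096), 2)
  sv <- matrix(runif(2 * 512), 2)
  fused <- concat_features(iv, sv)
  expect_equal(ncol(fused), 4608L)
  expect_equal(attr(fused, "image_dim"), 4096L)
  expect_equal(fused[, 1:4096], iv)
  expect_equal(fused[, 4097:4608], sv)

  # single-modal ablation: missing spectral block
  img_only <- concat_features(iv, NULL)
  expect_equal(dim(img_only), dim(iv))
  expect_equal(attr(img_only, "spectral_dim"), 0L)

  bad <- iv; bad[1, 1] <- NA
  expect_error(concat_features(bad, sv), class = "plum_data_error")
})

test_that("entropy weights follow the stated blend formula", {
  eq <- entropy_class_weights(rep(c("premium", "standard", "processing"), 10), 0.65)
  expect_equal(unname(eq), rep(1, 3), tolerance = 1e-12)

  imb <- rep(c("premium", "standard", "processing"), c(577, 5000, 4423))
  expect_equal(unname(entropy_class_weights(imb, 0)), rep(1, 3), tolerance = 1e-12)

  w <- entropy_class_weights(imb, 0.65)
  # independent hand computation of the blend
  f <- c(processing = 4423, standard = 5000, premium = 577) / 10000
  u <- (-log(f)) / mean(-log(f))
  expect_equal(unname(w[names(f)]), unname(0.35 + 0.65 * u), tolerance = 1e-12)
  expect_equal(names(which.max(w)), "premium")

  expect_error(entropy_class_weights(rep("standard", 10), 0.65),
               class = "plum_weight_error")
})

test_that("fusion head has the specified layer shapes and softmax output", {
  cfg <- fusion_config(image_dim = 4096, spectral_dim = 512)
  model <- build_fusion_head(cfg)
  expect_equal(dim(model$blocks[[1]]$W), c(4608L, 512L))
  expect_equal(length(model$blocks[[1]]$W) + length(model$blocks[[1]]$b),
               4608 * 512 + 512)
  expect_equal(dim(model$blocks[[2]]$W), c(512L, 256L))
  expect_equal(dim(model$out$W), c(256L, 3L))
  expect_false(is.null(model$blocks[[1]]$P))  # residual projection present

  X <- matrix(rnorm(4 * 4608), 4)
  p1 <- predict_grade(model, X)
  p2 <- predict_grade(model, X)
  expect_identical(p1, p2)  # dropout disabled at inference
  expect_equal(rowSums(p1$probs), rep(1, 4), tolerance = 1e-6)
  for (i in 1:4) {
    expect_equal(as.character(p1$grade[i]),
                 colnames(p1$probs)[which.max(p1$probs[i, ])])
  }
})

test_that("training separates easy classes and honors early stopping", {
  toy <- toy_grade_features()
  cfg <- fusion_config(image_dim = ncol(toy$X), spectral_dim = 0,
                       hidden_widths = c(16, 8), dropout_rate = 0.1,
                       batch_size = 16, max_epochs = 100, patience = 15, seed = 2)
  fit <- train_model(build_fusion_head(cfg), toy$X, toy$y, toy$X, toy$y, cfg)
  acc <- mean(as.character(predict_grade(fit$model, toy$X)$grade) == toy$y)
  expect_equal(acc, 1)
  expect_lte(attr(fit$history, "stop_epoch"), 100)
  # a nearest-centroid linear oracle certifies the problem is separable
  centroids <- t(vapply(unique(toy$y),
                        function(cl) colMeans(toy$X[toy$y == cl, ]),
                        numeric(ncol(toy$X))))
  oracle_pred <- rownames(centroids)[apply(toy$X, 1, function(x)
    which.min(colSums((t(centroids) - x)^2)))]
  expect_equal(mean(oracle_pred == toy$y), 1)
  expect_equal(acc, mean(oracle_pred == toy$y))

  # patience = 0: stops at the first epoch without validation improvement
  cfg0 <- fusion_config(image_dim = ncol(toy$X), spectral_dim = 0,
                        hidden_widths = c(8, 4), patience = 0, max_epochs = 50,
                        batch_size = 16, seed = 3)
  fit0 <- train_model(build_fusion_head(cfg0), toy$X, toy$y, toy$X, toy$y, cfg0)
  h <- fit0$history
  expect_lt(nrow(h), 50)
  expect_equal(attr(h, "stop_epoch"), nrow(h))
  expect_equal(nrow(h), attr(h, "best_epoch") + 1)

  # reproducibility: identical seeds give identical histories
  fit2 <- train_model(build_fusion_head(cfg), toy$X, toy$y, toy$X, toy$y, cfg)
  expect_identical(fit$history, fit2$history)

  # alpha = 0 weighting equals unweighted loss on a fixed batch
  w0 <- entropy_class_weights(toy$y, 0)
  fwd <- plumgrade:::head_forward(fit$model, toy$X, training = FALSE)
  y_int <- as.integer(factor(toy$y, levels = fit$model$classes))
  l_w <- plumgrade:::weighted_ce(fwd$probs, y_int, as.numeric(w0))
  l_u <- mean(-log(pmax(fwd$probs[cbind(seq_along(y_int), y_int)], 1e-12)))
  expect_equal(l_w, l_u, tolerance = 1e-9)
})

test_that("cross-validation partitions the training split into 5 folds", {
  toy <- toy_grade_features(n_per = 20, d = 6, seed = 8)
  cfg <- fusion_config(image_dim = 6, spectral_dim = 0, hidden_widths = c(8, 4),
                       batch_size = 16, max_epochs = 10, patience = 3,
                       folds = 5, seed = 13)
  cv <- crossvalidate(toy$X, toy$y, cfg)
  val_sets <- lapply(cv$folds, `[[`, "val_idx")
  expect_equal(vapply(val_sets, length, integer(1)), rep(12L, 5))
  expect_setequal(unlist(val_sets), seq_along(toy$y))
  expect_equal(sum(lengths(val_sets)), length(toy$y))  # pairwise disjoint
  cv2 <- crossvalidate(toy$X, toy$y, cfg)
  expect_identical(lapply(cv2$folds, `[[`, "val_idx"), val_sets)
  expect_named(cv$summary, c("mean", "sd"))

  expect_error(crossvalidate(toy$X[1:10, ], toy$y[1:10],
                             fusion_config(image_dim = 6, folds = 5)),
               class = "plum_fold_error")
})

test_that("prediction is batch-invariant and validates shapes", {
  toy <- toy_grade_features(n_per = 8, d = 5, seed = 4)
  cfg <- fusion_config(image_dim = 5, spectral_dim = 0, hidden_widths = c(8, 4),
                       batch_size = 8, max_epochs = 10, patience = 3, seed = 5)
  fit <- train_model(build_fusion_head(cfg), toy$X, toy$y, toy$X, toy$y, cfg)
  batch <- predict_grade(fit$model, toy$X)
  single <- predict_grade(fit$model, toy$X[7, ])
  expect_equal(batch$probs[7, ], single$probs[1, ], tolerance = 1e-12)
  expect_error(predict_grade(fit$model, matrix(0, 1, 9)),
               class = "plum_shape_error")
})
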