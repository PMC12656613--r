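# Confusion matrices, the accuracy/precision/recall/F1 system and model
# comparison.

test_that("confusion matrix counts truth rows against prediction columns", {
  cm <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), classes = c("A", "B"))
  expect_equal(unname(cm), matrix(c(1L, 0L, 1L, 1L), 2))

  y <- rep(c("premium", "standard", "processing"), c(4, 6, 5))
  perfect <- confusion_matrix(y, y)
  expect_equal(sum(diag(perfect)), length(y))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)
  expect_equal(unname(rowSums(perfect)), c(5L, 6L, 4L))  # per-class counts

  expect_error(confusion_matrix(c("A", "B"), c("A", "C"), classes = c("A", "B")),
               class = "plum_label_error")
  expect_error(confusion_matrix(c("A", "B"), c("A")), class = "plum_label_error")
})

test_that("metrics reproduce hand-computed binary values", {
  cm <- matrix(c(40L, 5L, 10L, 45L), 2,
               dimnames = list(truth = c("neg", "pos"), predicted = c("neg", "pos")))
  rep <- classification_metrics(cm)
  expect_equal(rep$accuracy, 0.85)
  pos <- rep$per_class[rep$per_class$class == "pos", ]
  expect_equal(pos$precision, 45 / 55)
  expect_equal(pos$recall, 0.9)
  expect_equal(pos$f1, 2 * (45 / 55) * 0.9 / (45 / 55 + 0.9), tolerance = 1e-12)

  lv <- c("processing", "standard", "premium")
  diag3 <- diag(c(5L, 8L, 3L))
  dimnames(diag3) <- list(truth = lv, predicted = lv)
  perfect <- classification_metrics(diag3)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_precision, 1)
  expect_equal(perfect$macro_recall, 1)
  expect_equal(perfect$macro_f1, 1)

  # zero-denominator convention: report 0 and flag
  degenerate <- matrix(c(3L, 2L, 0L, 0L), 2,
                       dimnames = list(truth = c("a", "b"), predicted = c("a", "b")))
  rep0 <- classification_metrics(degenerate)
  expect_equal(rep0$per_class$precision[2], 0)
  expect_true("b" %in% rep0$undefined_flags)
  expect_error(classification_metrics(matrix(0L, 0, 0)), class = "plum_domain_error")
})

test_that("metrics from the confusion matrix match a brute-force oracle", {
  set.seed(19)
  classes <- c("processing", "standard", "premium")
  for (rep_i in 1:5) {
    truth <- sample(classes, 60, replace = TRUE)
    pred <- ifelse(runif(60) < 0.7, truth, sample(classes, 60, replace = TRUE))
    r <- evaluate_predictions(truth, pred)
    # independent per-class counting straight from the label lists
    accs <- mean(truth == pred)
    expect_equal(r$accuracy, accs, tolerance = 1e-12)
    for (cl in classes) {
      tp <- sum(truth == cl & pred == cl)
      fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      row <- r$per_class[r$per_class$class == cl, ]
      expect_equal(row$tp, tp)
      expect_equal(row$precision, if (tp + fp == 0) 0 else tp / (tp + fp))
      expect_equal(row$recall, if (tp + fn == 0) 0 else tp / (tp + fn))
    }
    expect_equal(r$accuracy, sum(diag(r$confusion)) / sum(r$confusion))
  }
})

test_that("model comparison tabulates deltas and flags the best", {
  y <- rep(c("premium", "standard", "processing"), c(4, 10, 7))
  a <- evaluate_predictions(y, y, "fusion")
  wrong <- y; wrong[c(1, 5, 12)] <- c("standard", "processing", "premium")
  b <- evaluate_predictions(y, wrong, "image")

  same <- compare_models(list(a, a))
  expect_true(all(same$deltas$accuracy_delta_points == 0))

  cmp <- compare_models(list(a, b))
  expect_equal(nrow(cmp$table), 2)
  expect_equal(cmp$deltas$accuracy_delta_points,
               100 * (a$accuracy - b$accuracy))
  expect_equal(unname(cmp$best["accuracy"]), "fusion")

  # the headline fusion-vs-image gap: 100% vs 85.71% is +14.29 points
  n <- 14
  perfect <- evaluate_predictions(rep(c("a", "b"), 7), rep(c("a", "b"), 7), "fusion",
                                  classes = c("a", "b"))
  off <- rep(c("a", "b"), 7); off[1:2] <- c("b", "a")
  single <- evaluate_predictions(rep(c("a", "b"), 7), off, "image",
                                 classes = c("a", "b"))
  d <- compare_models(list(perfect, single))$deltas$accuracy_delta_points
  expect_equal(d, 100 * (1 - 12 / 14), tolerance = 1e-9)

  small <- evaluate_predictions(y[1:10], y[1:10], "tiny")
  expect_error(compare_models(list(a, small)), class = "plum_comparison_error")
})
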