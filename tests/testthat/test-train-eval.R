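test_that("zero epochs returns the model unchanged with empty history", {
  m <- tiny_model(wm = 1 / 16)
  set.seed(1)
  xs <- replicate(3, array(rnorm(32 * 32 * 3), c(32L, 32L, 3L)),
                  simplify = FALSE)
  fit <- train(m, list(x = xs, y = c("I", "II", "III")),
               cfg = train_config(epochs = 0L))
  expect_identical(hccanet:::get_params(fit$model), hccanet:::get_params(m))
  expect_identical(nrow(fit$history), 0L)
})

test_that("training history records one train/val row per epoch and the
           best-validation checkpoint is retained", {
  m <- tiny_model(wm = 1 / 16)
  set.seed(2)
  mk <- function(n) replicate(n, array(rnorm(32 * 32 * 3), c(32L, 32L, 3L)),
                              simplify = FALSE)
  fit <- train(m, list(x = mk(6), y = rep(c("I", "II", "III"), 2)),
               list(x = mk(3), y = c("I", "II", "III")),
               train_config(epochs = 3L, batch_size = 2L,
                            learning_rate = 1e-4, seed = 3L))
  expect_identical(nrow(fit$history), 3L)
  expect_true(all(is.finite(fit$history$val_acc)))
  expect_s3_class(fit$best, "hccanet")
})

test_that("divergence to non-finite loss aborts with a report", {
  m <- tiny_model(wm = 1 / 16)
  m$head$W[] <- 1e308  # overflow the logits on the first forward pass
  set.seed(3)
  xs <- replicate(4, array(rnorm(32 * 32 * 3), c(32L, 32L, 3L)),
                  simplify = FALSE)
  expect_error(
    train(m, list(x = xs, y = c("I", "II", "III", "I")),
          cfg = train_config(epochs = 2L, batch_size = 2L, seed = 1L)),
    "diverged")
})

test_that("stratified folds partition 630 samples into five folds of 126", {
  labels <- rep(c("I", "II", "III"), each = 210)
  folds <- make_folds(labels, k = 5L, seed = 7L)
  expect_identical(as.integer(table(folds)), rep(126L, 5L))
  for (f in 1:5)
    expect_identical(as.integer(table(labels[folds == f])), rep(42L, 3L))
  # every sample is validated exactly once
  expect_identical(sort(unique(folds)), 1:5)
  expect_length(folds, 630L)
  # deterministic under seed
  expect_identical(folds, make_folds(labels, k = 5L, seed = 7L))
  expect_false(identical(folds, make_folds(labels, k = 5L, seed = 8L)))
})

test_that("k equal to the dataset size gives leave-one-out folds", {
  labels <- c("I", "I", "II", "II", "III", "III")
  folds <- suppressWarnings(make_folds(labels, k = 6L, seed = 1L))
  expect_identical(sort(unique(folds)), 1:6)
  expect_identical(as.integer(table(folds)), rep(1L, 6L))
})

test_that("perfect predictions give unit metrics", {
  y <- rep(c("I", "II", "III"), each = 10)
  rep_ <- compute_metrics(y, y)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$per_class$precision, rep(1, 3))
  expect_equal(rep_$per_class$recall, rep(1, 3))
  expect_equal(rep_$per_class$f1, rep(1, 3))
  expect_length(rep_$flags, 0L)
})

test_that("the worked 6-sample example matches a hand confusion tally", {
  y_true <- c("I", "I", "II", "II", "III", "III")
  y_pred <- c("I", "II", "II", "II", "III", "I")
  r <- compute_metrics(y_true, y_pred)
  o <- oracle_confusion_metrics(y_true, y_pred, c("I", "II", "III"))
  expect_identical(unclass(unname(as.matrix(r$confusion))),
                   unclass(unname(o$confusion)))
  for (cl in c("I", "II", "III")) {
    row <- r$per_class[r$per_class$class == cl, ]
    expect_equal(row$precision, o$per_class[[cl]][["precision"]])
    expect_equal(row$recall, o$per_class[[cl]][["recall"]])
    expect_equal(row$f1, o$per_class[[cl]][["f1"]])
  }
  expect_equal(r$accuracy, o$accuracy)
})

test_that("single-class predictions give recall 1 for it and 0 elsewhere,
           with zero-denominator flags", {
  y_true <- rep(c("I", "II", "III"), each = 4)
  y_pred <- rep("II", 12)
  r <- compute_metrics(y_true, y_pred)
  expect_equal(r$per_class$recall[r$per_class$class == "II"], 1)
  expect_equal(r$per_class$recall[r$per_class$class != "II"], c(0, 0))
  expect_true(any(grepl("precision:", r$flags)))
})

test_that("metrics match the brute-force tally on random label vectors", {
  set.seed(101)
  for (trial in 1:50) {
    n <- sample(5:40, 1)
    y_true <- sample(c("I", "II", "III"), n, replace = TRUE)
    y_pred <- sample(c("I", "II", "III"), n, replace = TRUE)
    r <- compute_metrics(y_true, y_pred)
    o <- oracle_confusion_metrics(y_true, y_pred, c("I", "II", "III"))
    expect_equal(r$accuracy, o$accuracy)
    expect_identical(sum(r$confusion), n)
    expect_identical(unname(rowSums(r$confusion)),
                     vapply(c("I", "II", "III"),
                            function(cl) sum(y_true == cl), numeric(1),
                            USE.NAMES = FALSE))
    for (cl in c("I", "II", "III")) {
      row <- r$per_class[r$per_class$class == cl, ]
      expect_equal(row$precision, o$per_class[[cl]][["precision"]])
      expect_equal(row$recall, o$per_class[[cl]][["recall"]])
    }
  }
})

test_that("one-vs-rest AUC equals the exhaustive pairwise oracle and handles
           the degenerate score patterns", {
  y <- c(rep("I", 4), rep("II", 4), rep("III", 4))
  perfect <- matrix(0, 12, 3, dimnames = list(NULL, c("I", "II", "III")))
  perfect[cbind(1:12, rep(1:3, each = 4))] <- 1
  expect_equal(unname(roc_auc_ovr(y, perfect)$per_class), rep(1, 3))
  flat <- matrix(1 / 3, 12, 3, dimnames = list(NULL, c("I", "II", "III")))
  expect_equal(unname(roc_auc_ovr(y, flat)$per_class), rep(0.5, 3))
  set.seed(55)
  for (trial in 1:20) {
    n <- sample(6:20, 1)
    y <- sample(c("I", "II", "III"), n, replace = TRUE)
    while (length(unique(y)) < 3) y <- sample(c("I", "II", "III"), n, TRUE)
    sc <- matrix(round(runif(n * 3), 2), n, 3,
                 dimnames = list(NULL, c("I", "II", "III")))
    r <- roc_auc_ovr(y, sc)
    for (cl in c("I", "II", "III"))
      expect_identical(r$per_class[[cl]],
                       oracle_auc_pairwise(sc[, cl], y == cl))
    expect_identical(r$macro, mean(r$per_class))
  }
})

test_that("AUC is invariant under strictly monotone score transforms and
           flags absent classes", {
  set.seed(77)
  y <- sample(c("I", "II", "III"), 15, replace = TRUE)
  while (length(unique(y)) < 3) y <- sample(c("I", "II", "III"), 15, TRUE)
  sc <- matrix(runif(45), 15, 3, dimnames = list(NULL, c("I", "II", "III")))
  a1 <- roc_auc_ovr(y, sc)
  a2 <- roc_auc_ovr(y, exp(3 * sc))
  expect_equal(a1$per_class, a2$per_class)
  miss <- roc_auc_ovr(rep(c("I", "II"), 5), sc[1:10, ])
  expect_true(is.na(miss$per_class[["III"]]))
  expect_true(any(grepl("auc-undefined:III", miss$flags)))
  expect_false(is.na(miss$macro))
})

test_that("micro-averaged recall equals accuracy on single-label data", {
  set.seed(91)
  y_true <- sample(c("I", "II", "III"), 30, replace = TRUE)
  y_pred <- sample(c("I", "II", "III"), 30, replace = TRUE)
  r <- compute_metrics(y_true, y_pred)
  tp <- sum(diag(r$confusion))
  fn <- sum(r$confusion) - tp
  expect_equal(tp / (tp + fn), r$accuracy)
  expect_equal(sum(diag(r$confusion)) / sum(r$confusion), r$accuracy)
})

test_that("two-fold cross-validation runs the full pipeline per fold", {
  ds <- small_synth_set(4L, size = 32L, seed = 41L)
  res <- kfold_cv(ds, k = 2L,
                  model_cfg = hccanet_config(
                    backbone_config(input_size = c(32L, 32L, 3L),
                                    width_multiplier = 1 / 16), seed = 2L),
                  train_cfg = train_config(learning_rate = 2e-4, epochs = 2L,
                                           batch_size = 4L, seed = 3L),
                  seed = 4L)
  expect_length(res$reports, 2L)
  for (r in res$reports) {
    expect_s3_class(r, "metrics_report")
    expect_identical(sum(r$confusion), 6L)
  }
  expect_identical(as.integer(table(res$folds)), c(6L, 6L))
  expect_true(res$mean_accuracy >= 0 && res$mean_accuracy <= 1)
  # fold assignment reproducible under the same seed
  res2 <- make_folds(as.character(ds$labels), k = 2L, seed = 4L)
  expect_identical(res$folds, res2)
})
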