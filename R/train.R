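#' Training configuration
#'
#' Defaults follow the study protocol: Adam (beta1 = 0.9, beta2 = 0.99) at
#' learning rate 0.005, 100 epochs, batch size 32, categorical
#' cross-entropy. Epochs and batch size are routinely overridden for
#' CPU-scale runs.
#'
#' @param learning_rate positive step size.
#' @param beta1,beta2 Adam moment decays.
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size.
#' @param seed RNG seed governing shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.005, beta1 = 0.9, beta2 = 0.99,
                         epochs = 100L, batch_size = 32L, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 0L, batch_size >= 1L,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1)
  structure(list(learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "train_config")
}

as_xy <- function(set) {
  if (inherits(set, "labeled_dataset"))
    list(x = set$images, y = factor(set$labels, levels = grade_levels))
  else if (is.list(set) && !is.null(set$x) && !is.null(set$y))
    list(x = set$x, y = factor(set$y, levels = grade_levels))
  else stop("expected a labeled_dataset or a list(x=, y=)")
}

adam_step <- function(params, grads, state, cfg) {
  state$t <- state$t + 1L
  bc1 <- 1 - cfg$beta1^state$t
  bc2 <- 1 - cfg$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- cfg$beta1 * state$m[[nm]] + (1 - cfg$beta1) * g
    state$v[[nm]] <- cfg$beta2 * state$v[[nm]] + (1 - cfg$beta2) * g^2
    params[[nm]] <- params[[nm]] - cfg$learning_rate *
      (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + 1e-8)
  }
  list(params = params, state = state)
}

eval_on <- function(model, x, y) {
  n <- length(x)
  loss <- 0; correct <- 0L
  for (i in seq_len(n)) {
    p <- hccanet_forward(model, x[[i]])$probs
    loss <- loss - log(max(p[as.integer(y[i])], 1e-12))
    if (which.max(p) == as.integer(y[i])) correct <- correct + 1L
  }
  c(loss = loss / n, acc = correct / n)
}

#' Train the grading network
#'
#' Minibatch Adam under categorical cross-entropy. Only trainable
#' parameters (head, attention branch, unfrozen backbone layers) are
#' updated; frozen layers stay bit-identical. The per-epoch history records
#' train and validation loss/accuracy, and the parameter snapshot with the
#' best validation accuracy is retained. Training aborts with an error if
#' the loss becomes non-finite.
#'
#' @param model an `hccanet` model.
#' @param train_set,val_set `labeled_dataset`s (or `list(x=, y=)`) whose
#'   images match the model input size; `val_set` may be NULL.
#' @param cfg a [train_config()].
#' @return object of class `hccanet_fit`: `model` (final), `best` (best
#'   validation checkpoint; final model when no validation set), `history`
#'   data frame.
#' @export
train <- function(model, train_set, val_set = NULL,
                  cfg = train_config()) {
  tr <- as_xy(train_set)
  va <- if (!is.null(val_set)) as_xy(val_set)
  n <- length(tr$x)
  if (n == 0L) stop("empty training set")
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_loss = numeric(0),
                        val_acc = numeric(0))
  if (cfg$epochs == 0L)
    return(structure(list(model = model, best = model, history = history),
                     class = "hccanet_fit"))
  params <- get_params(model, trainable_only = TRUE)
  state <- list(t = 0L, m = list(), v = list())
  best_params <- params
  best_acc <- -Inf
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        batch <- ord[start:min(start + cfg$batch_size - 1L, n)]
        gsum <- NULL
        for (i in batch) {
          fwd <- hccanet_forward(model, tr$x[[i]], keep = TRUE)
          yi <- as.integer(tr$y[i])
          li <- -log(max(fwd$probs[yi], 1e-12))
          if (!is.finite(li) || !all(is.finite(fwd$logits)))
            stop("training diverged (non-finite loss) at epoch ", epoch)
          ep_loss <- ep_loss + li
          if (which.max(fwd$probs) == yi) ep_correct <- ep_correct + 1L
          dlogits <- fwd$probs
          dlogits[yi] <- dlogits[yi] - 1
          g <- hccanet_backward(model, fwd, dlogits)
          if (is.null(gsum)) gsum <- g[names(params)]
          else for (nm in names(params))
            gsum[[nm]] <- gsum[[nm]] + g[[nm]]
        }
        for (nm in names(params)) gsum[[nm]] <- gsum[[nm]] / length(batch)
        upd <- adam_step(params, gsum, state, cfg)
        params <- upd$params
        state <- upd$state
        model <- set_params(model, params)
      }
      val <- if (!is.null(va)) eval_on(model, va$x, va$y)
             else c(loss = NA_real_, acc = NA_real_)
      history[epoch, ] <- list(epoch, ep_loss / n, ep_correct / n,
                               val[["loss"]], val[["acc"]])
      track <- if (!is.null(va)) val[["acc"]] else ep_correct / n
      if (track > best_acc) {
        best_acc <- track
        best_params <- params
      }
    }
  })
  structure(list(model = model,
                 best = set_params(model, best_params),
                 history = history),
            class = "hccanet_fit")
}

#' Stratified fold assignment
#'
#' @param labels vector of class labels.
#' @param k number of folds (2 .. n).
#' @param seed RNG seed.
#' @return integer vector of fold ids in 1..k; within each class, sizes
#'   differ by at most one. Classes with fewer than `k` members are
#'   reported with a warning (they cannot appear in every fold).
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  stopifnot(k >= 2L, n >= k)
  folds <- integer(n)
  offset <- 0L
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        warning("class ", cl, " has fewer than ", k, " members")
      # round-robin continued across classes so overall fold sizes stay
      # balanced (and k = n degenerates to leave-one-out)
      folds[sample(idx)] <- (offset + seq_along(idx) - 1L) %% k + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}

#' k-fold cross-validation of the full pipeline
#'
#' Stratified folds; for each fold a fresh model is built, the standardizer
#' is fitted on that fold's training images only, the model is trained and
#' evaluated on the held-out fold. Images are resized to the model input
#' size on the fly when needed.
#'
#' @param dataset a `labeled_dataset`.
#' @param k number of folds (default 5).
#' @param model_cfg an [hccanet_config()].
#' @param train_cfg a [train_config()].
#' @param seed RNG seed for the fold assignment.
#' @return list with `reports` (one `metrics_report` per fold), `auc` (one
#'   [roc_auc_ovr()] result per fold), `folds`, `mean_accuracy`,
#'   `sd_accuracy`.
#' @export
kfold_cv <- function(dataset, k = 5L, model_cfg = hccanet_config(),
                     train_cfg = train_config(), seed = 1L) {
  ds <- as_xy(dataset)
  folds <- make_folds(as.character(ds$y), k = k, seed = seed)
  target <- model_cfg$backbone$input_size[1:2]
  sized <- lapply(ds$x, function(img) {
    if (identical(dim(img)[1:2], target)) img else resize_image(img, target)
  })
  reports <- list(); aucs <- list()
  for (f in seq_len(k)) {
    tr_idx <- which(folds != f)
    va_idx <- which(folds == f)
    std <- fit_standardizer(sized[tr_idx])
    xs <- lapply(sized, function(img) apply_standardizer(std, img))
    model <- build_hccanet(model_cfg)
    fit <- train(model, list(x = xs[tr_idx], y = ds$y[tr_idx]),
                 list(x = xs[va_idx], y = ds$y[va_idx]), train_cfg)
    probs <- predict(fit$best, xs[va_idx])
    pred <- grade_levels[apply(probs, 1L, which.max)]
    reports[[f]] <- compute_metrics(ds$y[va_idx], pred)
    aucs[[f]] <- roc_auc_ovr(ds$y[va_idx], probs)
  }
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  list(reports = reports, auc = aucs, folds = folds,
       mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc))
}
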