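#' Confusion-matrix metrics for 3-grade predictions
#'
#' Builds the confusion matrix and, per class, precision `TP/(TP+FP)`,
#' recall `TP/(TP+FN)` and `F1 = 2PR/(P+R)`, plus overall accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`. Any zero-denominator rate is reported as 0 and
#' the affected quantity is listed in `flags`.
#'
#' @param y_true,y_pred equal-length vectors of grade labels.
#' @param labels label universe (default the three grades).
#' @return object of class `metrics_report`: `confusion` (rows = true),
#'   `per_class` data frame, `accuracy`, `flags`.
#' @export
compute_metrics <- function(y_true, y_pred, labels = grade_levels) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred differ in length")
  y_true <- factor(as.character(y_true), levels = labels)
  y_pred <- factor(as.character(y_pred), levels = labels)
  if (anyNA(y_true) || anyNA(y_pred))
    stop("labels outside the grade set")
  confusion <- table(true = y_true, predicted = y_pred)
  n <- length(y_true)
  flags <- character(0)
  per_class <- do.call(rbind, lapply(labels, function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    safe <- function(num, den, what) {
      if (den == 0) {
        flags <<- c(flags, paste0(what, ":", cl))
        0
      } else num / den
    }
    p <- safe(tp, tp + fp, "precision")
    r <- safe(tp, tp + fn, "recall")
    f1 <- if (p + r == 0) {
      flags <<- c(flags, paste0("f1:", cl)); 0
    } else 2 * p * r / (p + r)
    data.frame(class = cl, precision = p, recall = r, f1 = f1)
  }))
  structure(list(confusion = confusion, per_class = per_class,
                 accuracy = sum(diag(confusion)) / n, n = n,
                 flags = flags),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("accuracy:", round(x$accuracy, 4), "on", x$n, "samples\n")
  print(x$per_class, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' One-vs-rest ROC AUC
#'
#' Per class, the area under the ROC curve of that class's score against
#' all other samples, computed by the rank (Mann-Whitney) statistic with
#' midrank tie handling; plus the unweighted macro average over classes
#' present in `y_true`. A class absent from `y_true` has undefined AUC
#' (`NA`) and is flagged.
#'
#' @param y_true vector of grade labels.
#' @param class_scores n x K numeric matrix of class scores/probabilities;
#'   columns named by class (or assumed in grade order).
#' @param labels label universe (default the three grades).
#' @return list with `per_class` (named numeric, possibly `NA`), `macro`
#'   and `flags`.
#' @export
roc_auc_ovr <- function(y_true, class_scores, labels = grade_levels) {
  class_scores <- as.matrix(class_scores)
  if (is.null(colnames(class_scores))) colnames(class_scores) <- labels
  y_true <- as.character(y_true)
  if (nrow(class_scores) != length(y_true))
    stop("scores and labels differ in length")
  flags <- character(0)
  per_class <- vapply(labels, function(cl) {
    pos <- y_true == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) {
      flags <<- c(flags, paste0("auc-undefined:", cl))
      return(NA_real_)
    }
    r <- rank(class_scores[, cl])     # midranks for ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  list(per_class = per_class,
       macro = mean(per_class, na.rm = TRUE),
       flags = flags)
}
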