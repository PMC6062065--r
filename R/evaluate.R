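#' Support-weighted classification metrics from predictions
#'
#' Computes accuracy plus per-class precision, recall and F-measure, and
#' their support-weighted averages (each class's metric weighted by its
#' true-instance count) — the reporting convention of standard ML
#' toolkits.  A class never predicted gets precision 0.
#'
#' @param truth 0/1 true labels.
#' @param pred 0/1 predicted labels.
#' @return list with `accuracy`, `confusion` (2x2 matrix, rows = truth),
#'   `per_class` data frame and weighted `precision`, `recall`,
#'   `f_measure`.
#' @export
confusion_metrics <- function(truth, pred) {
  truth <- as.integer(truth)
  pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred),
            all(truth %in% 0:1), all(pred %in% 0:1))
  cm <- table(factor(truth, 0:1), factor(pred, 0:1))
  cm <- matrix(as.numeric(cm), 2, 2,
               dimnames = list(truth = c("0", "1"), pred = c("0", "1")))
  support <- rowSums(cm)
  per <- lapply(1:2, function(i) {
    tp <- cm[i, i]
    prec <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec <- if (support[i] > 0) tp / support[i] else 0
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f_measure = f)
  })
  per_class <- data.frame(class = c(0L, 1L), support = as.numeric(support),
                          do.call(rbind, per))
  w <- support / sum(support)
  list(
    accuracy = sum(diag(cm)) / sum(cm),
    confusion = cm,
    per_class = per_class,
    precision = sum(w * per_class$precision),
    recall = sum(w * per_class$recall),
    f_measure = sum(w * per_class$f_measure)
  )
}

#' Area under the ROC curve by trapezoidal integration
#'
#' Sweeps all score thresholds (ties collapsed to a single ROC point) and
#' integrates TPR over FPR with the trapezoid rule.
#'
#' @param scores continuous classifier scores, larger = more class 1.
#' @param truth 0/1 true labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(truth)
  stopifnot(length(scores) == length(truth), all(truth %in% 0:1))
  n1 <- sum(truth == 1L)
  n0 <- sum(truth == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes required for ROC area")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  last_of_tie <- !duplicated(s, fromLast = TRUE)
  tpr <- c(0, tp[last_of_tie] / n1)
  fpr <- c(0, fp[last_of_tie] / n0)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Stratified k-fold cross-validation of the random forest
#'
#' Splits each class separately into `folds` parts (shuffled under
#' `rng_seed`), trains on the remaining folds and predicts the held-out
#' fold.  Reports per-fold metrics and, from the pooled out-of-fold
#' predictions, the five weighted summary metrics: accuracy, precision,
#' recall, F-measure and ROC area (computed from the continuous vote
#' scores).
#'
#' @param X feature matrix.
#' @param y 0/1 labels, at least `folds` instances per class.
#' @param folds number of folds (default 10).
#' @param rng_seed integer seed controlling fold assignment and per-fold
#'   forest training.
#' @param ... passed to [train_forest()] (e.g. `t`, `features_per_split`).
#' @return an object of class `ggi_evaluation`: list with `weighted`
#'   (accuracy, precision, recall, f_measure, roc_area), `per_fold` data
#'   frame, `confusion` (pooled), `predictions`, `folds`, `rng_seed`.
#' @export
cross_validate <- function(X, y, folds = 10L, rng_seed = 1L, ...) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (min(table(factor(y, 0:1))) < folds) {
    stop("need at least `folds` instances of each class for stratified CV")
  }
  fold_of <- integer(length(y))
  fold_of[y == 0L] <- with_seed(derive_seed(rng_seed, "fold0"),
                                sample(rep_len(seq_len(folds), sum(y == 0L))))
  fold_of[y == 1L] <- with_seed(derive_seed(rng_seed, "fold1"),
                                sample(rep_len(seq_len(folds), sum(y == 1L))))

  pred_label <- integer(length(y))
  pred_score <- numeric(length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_of == f
    model <- train_forest(X[!test, , drop = FALSE], y[!test],
                          rng_seed = derive_seed(rng_seed, paste0("train", f)),
                          ...)
    p <- predict(model, X[test, , drop = FALSE])
    pred_label[test] <- p$labels
    pred_score[test] <- p$scores
    m <- confusion_metrics(y[test], p$labels)
    per_fold[[f]] <- data.frame(
      fold = f, n = sum(test), accuracy = m$accuracy,
      precision = m$precision, recall = m$recall, f_measure = m$f_measure,
      roc_area = roc_auc(p$scores, y[test]))
  }
  pooled <- confusion_metrics(y, pred_label)
  structure(
    list(weighted = list(accuracy = pooled$accuracy,
                         precision = pooled$precision,
                         recall = pooled$recall,
                         f_measure = pooled$f_measure,
                         roc_area = roc_auc(pred_score, y)),
         per_fold = do.call(rbind, per_fold),
         confusion = pooled$confusion,
         predictions = data.frame(truth = y, fold = fold_of,
                                  label = pred_label, score = pred_score),
         folds = as.integer(folds),
         rng_seed = as.integer(rng_seed)),
    class = "ggi_evaluation"
  )
}

#' @export
print.ggi_evaluation <- function(x, ...) {
  w <- x$weighted
  cat(sprintf(
    "ggi_evaluation (%d-fold CV): accuracy %.3f, precision %.3f, recall %.3f, F %.3f, ROC area %.3f\n",
    x$folds, w$accuracy, w$precision, w$recall, w$f_measure, w$roc_area))
  invisible(x)
}

#' Export an evaluation report as JSON
#'
#' Writes the five weighted metrics, the pooled confusion matrix, per-fold
#' detail and the fold-assignment seed.
#'
#' @param ev a `ggi_evaluation`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(ev, path) {
  stopifnot(inherits(ev, "ggi_evaluation"))
  payload <- list(
    weighted = ev$weighted,
    confusion = list(truth0 = as.list(setNames(ev$confusion[1, ], c("pred0", "pred1"))),
                     truth1 = as.list(setNames(ev$confusion[2, ], c("pred0", "pred1")))),
    per_fold = ev$per_fold,
    folds = ev$folds,
    rng_seed = ev$rng_seed)
  writeLines(jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                              dataframe = "rows"), path)
  invisible(path)
}
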