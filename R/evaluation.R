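#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integers, or vectors of predicted and
#'   true classes via [confusion_from_labels()].
#' @return List of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn),
            class = "confusion_counts")
}

#' Tabulate confusion counts from predicted and true classes
#'
#' @param predicted,truth vectors over \{`secretory`, `non_secretory`\};
#'   `secretory` is the positive class.
#' @export
confusion_from_labels <- function(predicted, truth) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  confusion_counts(
    tp = sum(predicted == "secretory" & truth == "secretory"),
    tn = sum(predicted == "non_secretory" & truth == "non_secretory"),
    fp = sum(predicted == "secretory" & truth == "non_secretory"),
    fn = sum(predicted == "non_secretory" & truth == "secretory"))
}

#' Prediction-quality statistics from confusion counts
#'
#' Computes sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP),
#' accuracy Acc = (TP+TN)/total, and the Matthews correlation coefficient.
#' Also reports the class-wise true-prediction rates: for the positive class
#' Upsilon+ = 1 - FN/(TP+FN), for the negative class Upsilon- =
#' 1 - FP/(TN+FP), and the overall rate Upsilon, which is identically Acc.
#' MCC is `NA` (undefined) when any marginal of the confusion table is zero.
#'
#' @param counts a [confusion_counts()].
#' @return List of class `metric_report` with `Sn`, `Sp`, `Acc`, `MCC`,
#'   `Upsilon_plus`, `Upsilon_minus`, `Upsilon` and the input counts.
#' @examples
#' sp_metrics(confusion_counts(tp = 159, tn = 148, fp = 22, fn = 31))
#' @export
sp_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  # double precision: the MCC denominator overflows 32-bit integers
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  pos <- tp + fn; neg <- tn + fp
  sn <- if (pos > 0) tp / pos else NA_real_
  sp <- if (neg > 0) tn / neg else NA_real_
  acc <- (tp + tn) / (tp + tn + fp + fn)
  denom <- (tp + fp) * (fn + tn) * (fp + tn) * (tp + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else NA_real_
  structure(list(Sn = sn, Sp = sp, Acc = acc, MCC = mcc,
                 Upsilon_plus = sn, Upsilon_minus = sp, Upsilon = acc,
                 counts = counts),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 2, ...) {
  cat(sprintf("Sn %.*f  Sp %.*f  Acc %.*f  MCC %s\n",
              digits, x$Sn, digits, x$Sp, digits, x$Acc,
              if (is.na(x$MCC)) "NA" else sprintf("%.*f", digits, x$MCC)))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Sweeps thresholds over the unique scores (predicting `secretory` when
#' score >= threshold) and computes the trapezoidal area. The curve starts
#' at (0,0) and ends at (1,1).
#'
#' @param scores numeric scores, larger = more secretory-like.
#' @param labels class labels over \{`secretory`, `non_secretory`\}.
#' @return List with `curve` (data.frame of FPR, TPR) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == "secretory"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC requires both classes to be present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(pos & scores >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(!pos & scores >= t) / n_neg, numeric(1))
  curve <- data.frame(FPR = c(0, fpr, 1), TPR = c(0, tpr, 1))
  curve <- curve[order(curve$FPR, curve$TPR), ]
  auc <- sum(diff(curve$FPR) * (utils::head(curve$TPR, -1) +
                                  utils::tail(curve$TPR, -1)) / 2)
  list(curve = curve, auc = auc)
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin into k folds; the deal continues across classes so the
# total fold sizes stay balanced too.
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Run a validation protocol on an encoded dataset
#'
#' Trains and evaluates the classifier under one of three protocols:
#' `self_consistency` (train and test on the full set), `kfold` (stratified
#' k-fold cross-validation, default k = 10, pooled confusion counts plus the
#' average of per-fold accuracies) or `jackknife` (leave-one-out; each
#' sample is predicted by a model trained on all others).
#'
#' @param x feature matrix.
#' @param labels class labels over \{`secretory`, `non_secretory`\}.
#' @param protocol one of `"self_consistency"`, `"kfold"`, `"jackknife"`.
#' @param k number of folds for `kfold`.
#' @param seed seed controlling fold assignment and weight initialization.
#' @param ... passed to [sp_classifier()] (e.g. `max_epochs`, `hidden`).
#' @return List with `protocol`, `folds` (list of per-fold
#'   `confusion_counts`; one entry for self-consistency, n for jackknife),
#'   `pooled` (pooled counts), `metrics` ([sp_metrics()] of the pooled
#'   counts), `mean_accuracy` (average of per-fold accuracies), and
#'   `scores`/`truth` for ROC analysis.
#' @export
run_protocol <- function(x, labels,
                         protocol = c("self_consistency", "kfold", "jackknife"),
                         k = 10L, seed = 1L, ...) {
  protocol <- match.arg(protocol)
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  stopifnot(n == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("dataset must contain both classes", call. = FALSE)
  }

  if (protocol == "self_consistency") {
    fit <- sp_classifier(x, labels, seed = seed, ...)
    pred <- predict(fit, x)
    cc <- confusion_from_labels(pred$class, labels)
    return(list(protocol = protocol, folds = list(cc), pooled = cc,
                metrics = sp_metrics(cc), mean_accuracy = sp_metrics(cc)$Acc,
                scores = pred$score, truth = labels, model = fit))
  }

  if (protocol == "jackknife") {
    k <- n
    fold <- seq_len(n)
  } else {
    k <- as.integer(k)
    if (k > n) stop("k must not exceed the number of samples", call. = FALSE)
    # k == n is leave-one-out; use identity folds so it coincides exactly
    # with the jackknife protocol
    fold <- if (k == n) seq_len(n) else stratified_folds(labels, k, seed)
  }

  per_fold <- vector("list", k)
  scores <- numeric(n)
  pred_class <- character(n)
  for (f in seq_len(k)) {
    test <- which(fold == f)
    train <- setdiff(seq_len(n), test)
    if (length(unique(labels[train])) < 2L) {
      stop("training split lost a class; dataset too small for ", protocol,
           call. = FALSE)
    }
    fit <- sp_classifier(x[train, , drop = FALSE], labels[train],
                         seed = seed + f, ...)
    pred <- predict(fit, x[test, , drop = FALSE])
    scores[test] <- pred$score
    pred_class[test] <- pred$class
    per_fold[[f]] <- confusion_from_labels(pred$class, labels[test])
  }
  pooled <- confusion_from_labels(pred_class, labels)
  fold_acc <- vapply(per_fold, function(cc) sp_metrics(cc)$Acc, numeric(1))
  list(protocol = protocol, folds = per_fold, pooled = pooled,
       metrics = sp_metrics(pooled), mean_accuracy = mean(fold_acc),
       scores = scores, truth = labels)
}
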