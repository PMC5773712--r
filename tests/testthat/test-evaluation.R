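test_that("metrics recover the standard confusion-table statistics", {
  m <- sp_metrics(confusion_counts(tp = 5648, tn = 1297, fp = 392, fn = 92))
  expect_equal(round(m$Sn, 2), 0.98)
  expect_equal(round(m$Sp, 2), 0.77)
  expect_equal(round(m$MCC, 2), 0.81)
  m2 <- sp_metrics(confusion_counts(tp = 159, tn = 148, fp = 22, fn = 31))
  expect_equal(round(m2$Acc, 2), 0.85)
  expect_equal(round(m2$MCC, 2), 0.71)
})

test_that("a perfect prediction gives unit rates across every statistic", {
  m <- sp_metrics(confusion_counts(tp = 50, tn = 30, fp = 0, fn = 0))
  expect_equal(m$Sn, 1)
  expect_equal(m$Sp, 1)
  expect_equal(m$Acc, 1)
  expect_equal(m$MCC, 1)
  expect_equal(m$Upsilon, 1)
  expect_equal(m$Upsilon_plus, 1)
  expect_equal(m$Upsilon_minus, 1)
})

test_that("MCC is undefined (NA) on a zero marginal; other statistics survive", {
  m <- sp_metrics(confusion_counts(tp = 10, tn = 0, fp = 0, fn = 5))
  expect_true(is.na(m$MCC))
  expect_equal(m$Sn, 10 / 15)
  expect_equal(m$Acc, 10 / 15)
})

test_that("accuracy equals the overall true-prediction rate on random tables", {
  set.seed(10)
  for (i in 1:200) {
    tp <- sample(0:500, 1); tn <- sample(0:500, 1)
    fp <- sample(0:500, 1); fn <- sample(0:500, 1)
    if (tp + tn + fp + fn == 0) next
    m <- sp_metrics(confusion_counts(tp, tn, fp, fn))
    # overall rate written in terms of the class totals and miscounts
    t_pos <- tp + fn; t_neg <- tn + fp
    expect_equal(m$Upsilon, 1 - (fn + fp) / (t_pos + t_neg))
    expect_equal(m$Acc, m$Upsilon)
  }
})

test_that("the two MCC parameterizations agree on random tables", {
  set.seed(11)
  for (i in 1:200) {
    tp <- sample(1:500, 1); tn <- sample(1:500, 1)
    fp <- sample(1:500, 1); fn <- sample(1:500, 1)
    m <- sp_metrics(confusion_counts(tp, tn, fp, fn))
    t_pos <- tp + fn; t_neg <- tn + fp
    mcc_alt <- (1 - (fn / t_pos + fp / t_neg)) /
      sqrt((1 + (fp - fn) / t_pos) * (1 + (fn - fp) / t_neg))
    expect_equal(m$MCC, mcc_alt, tolerance = 1e-12)
  }
})

test_that("confusion counts tabulated from labels match the definitions", {
  pred <- c("secretory", "secretory", "non_secretory", "non_secretory", "secretory")
  truth <- c("secretory", "non_secretory", "non_secretory", "secretory", "secretory")
  cc <- confusion_from_labels(pred, truth)
  expect_equal(cc$TP, 2L)
  expect_equal(cc$TN, 1L)
  expect_equal(cc$FP, 1L)
  expect_equal(cc$FN, 1L)
})

test_that("ROC endpoints, symmetry and degenerate separations behave", {
  labels <- rep(c("secretory", "non_secretory"), each = 10)
  perfect <- c(runif(10, 0.6, 1), runif(10, 0, 0.4))
  r <- roc_curve(perfect, labels)
  expect_equal(r$auc, 1)
  expect_equal(r$curve$FPR[1], 0)
  expect_equal(r$curve$TPR[1], 0)
  expect_equal(r$curve$FPR[nrow(r$curve)], 1)
  expect_equal(r$curve$TPR[nrow(r$curve)], 1)
  # reversing scores complements the area
  set.seed(15)
  scores <- runif(20)
  r1 <- roc_curve(scores, labels)
  r2 <- roc_curve(-scores, labels)
  expect_equal(r2$auc, 1 - r1$auc, tolerance = 1e-12)
  expect_error(roc_curve(scores, rep("secretory", 20)), "both classes")
})

test_that("labels independent of scores give chance-level AUC", {
  set.seed(16)
  scores <- runif(2000)
  labels <- sample(rep(c("secretory", "non_secretory"), each = 1000))
  expect_equal(roc_curve(scores, labels)$auc, 0.5, tolerance = 0.05)
})

test_that("AUC agrees with the pairwise-ranking oracle and with pROC", {
  set.seed(17)
  labels <- sample(rep(c("secretory", "non_secretory"), c(30, 25)))
  scores <- round(runif(55), 2) # duplicates force tie handling
  r <- roc_curve(scores, labels)
  expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-9)
  proc_auc <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("non_secretory", "secretory"),
    direction = "<", quiet = TRUE)))
  expect_equal(r$auc, proc_auc, tolerance = 1e-9)
})

test_that("self-consistency on separable synthetic data is perfect", {
  d <- make_clouds(n_per_class = 15)
  res <- run_protocol(d$x, d$labels, "self_consistency", seed = 1,
                      hidden = 8, max_epochs = 150)
  expect_equal(res$metrics$Acc, 1)
  expect_equal(res$mean_accuracy, 1)
})

test_that("k-fold folds are a disjoint stratified cover", {
  labels <- rep(c("secretory", "non_secretory"), c(18, 12))
  fold <- sigscan:::stratified_folds(labels, 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 30L)
  # every index in exactly one fold; classes spread evenly
  expect_equal(as.vector(table(fold)), rep(6L, 5))
  sec_per_fold <- vapply(1:5, function(f) sum(labels[fold == f] == "secretory"),
                         integer(1))
  expect_true(all(sec_per_fold %in% 3:4)) # 18 positives over 5 folds
  expect_equal(sum(sec_per_fold), 18L)
})

test_that("k-fold cross-validation pools a full cover of predictions", {
  d <- make_clouds(n_per_class = 20, dim = 15)
  res <- run_protocol(d$x, d$labels, "kfold", k = 5, seed = 2,
                      hidden = 5, max_epochs = 60)
  cc <- res$pooled
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 40L)
  expect_length(res$folds, 5L)
  expect_gt(res$metrics$Acc, 0.8)
  expect_error(run_protocol(d$x, d$labels, "kfold", k = 100), "exceed")
})

test_that("leave-one-out coincides with k-fold at k = n", {
  d <- make_clouds(n_per_class = 6, dim = 8)
  jack <- run_protocol(d$x, d$labels, "jackknife", seed = 5,
                       hidden = 3, max_epochs = 25)
  kf <- run_protocol(d$x, d$labels, "kfold", k = 12, seed = 5,
                     hidden = 3, max_epochs = 25)
  expect_equal(jack$scores, kf$scores)
  expect_equal(jack$pooled, kf$pooled)
  expect_length(jack$folds, 12L)
})
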