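test_that("confusion tallies the 2x2 table", {
  c1 <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(unclass(c1)[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))
  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$fp + perfect$fn, 0L)
  inv <- confusion(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(c(inv$tp, inv$tn), c(0L, 0L))
  expect_equal(c(inv$fp, inv$fn), c(2L, 2L))
  expect_error(confusion(c(1, 0), c(1)), "equal length")
})

test_that("metrics match direct arithmetic on hand and random confusions", {
  m <- compute_metrics(confusion(rep(c(1, 0), each = 50),
                                 c(rep(1, 25), rep(0, 25), rep(0, 25), rep(1, 25))))
  expect_equal(m$accuracy, 50)
  expect_equal(m$mcc, 0)

  perfect <- compute_metrics(confusion(rep(c(1, 0), each = 50),
                                       rep(c(1, 0), each = 50)))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$sensitivity, 100)
  expect_equal(perfect$specificity, 100)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)

  cm <- structure(list(tp = 45L, tn = 40L, fp = 10L, fn = 5L),
                  class = "confusion_counts")
  m <- compute_metrics(cm)
  o <- oracle_metrics(45, 40, 10, 5)
  expect_equal(m$sensitivity, 90)
  expect_equal(m$specificity, 80)
  expect_equal(m$accuracy, 85)
  expect_equal(m$mcc, o$mcc)

  set.seed(81)
  for (i in 1:200) {
    cts <- as.list(sample(1:40, 4, replace = TRUE))
    names(cts) <- c("tp", "tn", "fp", "fn")
    cm <- structure(cts, class = "confusion_counts")
    m <- compute_metrics(cm)
    o <- oracle_metrics(cts$tp, cts$tn, cts$fp, cts$fn)
    expect_equal(m$accuracy, o$acc)
    expect_equal(m$sensitivity, o$sn)
    expect_equal(m$specificity, o$sp)
    expect_equal(m$mcc, o$mcc)
    expect_equal(m$recall, o$recall)
    expect_equal(m$sensitivity, m$recall * 100)
    expect_gte(m$mcc, -1)
    expect_lte(m$mcc, 1)
  }
})

test_that("MCC flips sign under prediction inversion", {
  set.seed(82)
  labels <- rbinom(60, 1, 0.5)
  preds <- ifelse(runif(60) < 0.8, labels, 1 - labels)
  m <- compute_metrics(confusion(labels, preds))
  m_inv <- compute_metrics(confusion(labels, 1 - preds))
  expect_equal(m_inv$mcc, -m$mcc)
})

test_that("zero denominators yield NA with a warning, never silent zero", {
  cm <- confusion(c(1, 1, 1), c(0, 0, 0))  # nothing predicted positive
  ws <- capture_warnings(m <- compute_metrics(cm))
  expect_true(any(grepl("undefined", ws)))
  expect_true(is.na(m$precision))
  expect_true(is.na(m$mcc))
  expect_equal(m$sensitivity, 0)
})

test_that("ROC/AUC handles perfect ranking, total ties and the pair oracle", {
  labels <- c(1, 1, 0, 0)
  perfect <- roc_curve_auc(labels, c(0.9, 0.8, 0.2, 0.1))
  expect_equal(perfect$auc, 1)
  tied <- roc_curve_auc(labels, rep(0.5, 4))
  expect_equal(tied$auc, 0.5)
  expect_error(roc_curve_auc(c(1, 1), c(0.1, 0.2)), "both classes")

  set.seed(83)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 1)  # coarse grid forces ties
    r <- roc_curve_auc(labels, scores)
    expect_equal(r$auc, oracle_auc(labels, scores), tolerance = 1e-12)
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(tail(r$curve$tpr, 1), 1)
  }
})

test_that("stratified K-fold partitions every class evenly and reproducibly", {
  d <- small_signal_data(n_per_class = 5)
  folds <- stratified_kfold(d, folds = 5, seed = 1)
  for (f in folds) {
    expect_equal(sum(d$labels[f$test] == 1), 1)
    expect_equal(sum(d$labels[f$test] == 0), 1)
    expect_setequal(c(f$train, f$test), seq_along(d$ids))
  }
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(all_test, seq_along(d$ids))
  expect_identical(stratified_kfold(d, 5, seed = 1), folds)
  expect_false(identical(stratified_kfold(d, 5, seed = 2), folds))
  expect_error(stratified_kfold(d, folds = 6), ">= 6")
})

test_that("run_cv aggregates per-fold metrics by arithmetic mean", {
  d <- small_signal_data(n_per_class = 15)
  cv <- run_cv(d, use_pca = TRUE, n_components = 8,
               model_cfg = fast_dnn(epochs = 25), folds = 3, seed = 11)
  expect_length(cv$per_fold, 3)
  for (f in c("accuracy", "mcc", "auc")) {
    vals <- vapply(cv$per_fold, `[[`, numeric(1), f)
    expect_equal(cv$mean[[f]], mean(vals, na.rm = TRUE), tolerance = 1e-9)
  }
  expect_equal(cv$folds, 3L)
  expect_equal(cv$seed, 11L)
})

test_that("single-encoder mode and the ablation table mirror the protocol", {
  d <- small_signal_data(n_per_class = 12)
  cv_kmer <- run_cv(d, use_pca = FALSE, model_cfg = fast_dnn(epochs = 10),
                    folds = 2, seed = 3, only = "kmer")
  expect_length(cv_kmer$per_fold, 2)
  tab <- suppressWarnings(  # tiny folds can make single-encoder F1/MCC NA
    ablation_cv(d, n_components = 5, model_cfg = fast_dnn(epochs = 5),
                folds = 2, seed = 3))
  expect_equal(tab$method,
               c("kmer", "rc_kmer", "pse_dnc", "pse_tnc", "tac", "tcc", "dcc",
                 "hybrid", "hybrid_pca"))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 100))
})

test_that("baseline classifier adapters run through the same CV harness", {
  skip_if_not_installed("e1071")
  skip_if_not_installed("class")
  d <- small_signal_data(n_per_class = 15)
  for (clf in c("nb", "knn")) {
    cv <- suppressWarnings(
      run_cv(d, use_pca = FALSE, folds = 2, seed = 5, classifier = clf))
    expect_true(cv$mean$accuracy >= 0 && cv$mean$accuracy <= 100)
    expect_true(cv$mean$auc >= 0 && cv$mean$auc <= 1)
  }
})

test_that("independent evaluation checks inputs and flags id leakage", {
  d <- small_signal_data(n_per_class = 20)
  fm <- encode_hybrid(d)
  pca <- fit_pca(fm, 10)
  model <- train_dnn(transform_pca(pca, fm), d$labels, fast_dnn(epochs = 40))
  # evaluating on the training data itself: optimistic upper bound
  m_train <- evaluate_independent(model, pca, d)
  expect_gte(m_train$accuracy, 50)
  expect_warning(evaluate_independent(model, pca, d, train_ids = d$ids),
                 "shares")
  expect_error(evaluate_independent(model, pca, list()), "labeled_dataset")
})
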