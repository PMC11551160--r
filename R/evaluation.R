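# Performance evaluation: confusion-matrix metrics (accuracy, sensitivity,
# specificity, MCC, precision/recall/F1), threshold-sweep ROC with trapezoidal
# AUC, stratified K-fold cross-validation, the full-pipeline CV driver
# (encode -> PCA per fold -> train -> test), per-encoder ablation, and thin
# adapters over standard classifiers for the comparison harness.

#' Confusion counts
#'
#' Standard 2x2 tally; `tp` counts label = 1 and prediction = 1.
#'
#' @param labels binary 0/1 vector.
#' @param predictions binary 0/1 vector of the same length.
#' @return object of class `confusion_counts` (tp, tn, fp, fn).
#' @export
confusion <- function(labels, predictions) {
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (length(labels) != length(predictions) || length(labels) < 1L) {
    stop("labels and predictions must have equal length >= 1", call. = FALSE)
  }
  if (!all(labels %in% 0:1) || !all(predictions %in% 0:1)) {
    stop("labels and predictions must be binary (0/1)", call. = FALSE)
  }
  structure(list(
    tp = sum(labels == 1L & predictions == 1L),
    tn = sum(labels == 0L & predictions == 0L),
    fp = sum(labels == 0L & predictions == 1L),
    fn = sum(labels == 1L & predictions == 0L)
  ), class = "confusion_counts")
}

ratio_or_na <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); reported as NA", what),
            call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity and specificity on the percent (x100) scale, MCC in
#' [-1, 1], and precision/recall/F1 as proportions (F1 is also conventionally
#' reported x100). Sensitivity is identically recall x 100. Undefined ratios
#' (zero denominators) are reported as `NA` with a warning, never silently 0.
#'
#' @param c a `confusion_counts` object.
#' @return object of class `metric_set`: accuracy, sensitivity, specificity,
#'   mcc, precision, recall, f1, auc (`NA` unless filled in by a caller that
#'   has scores).
#' @export
compute_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  tp <- as.numeric(c$tp); tn <- as.numeric(c$tn)
  fp <- as.numeric(c$fp); fn <- as.numeric(c$fn)
  n <- tp + tn + fp + fn
  acc <- ratio_or_na(tp + tn, n, "accuracy") * 100
  sn <- ratio_or_na(tp, tp + fn, "sensitivity") * 100
  sp <- ratio_or_na(tn, tn + fp, "specificity") * 100
  recall <- sn / 100
  precision <- ratio_or_na(tp, tp + fp, "precision")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    if (!is.na(precision) && !is.na(recall)) {
      warning("F1 undefined (precision + recall = 0); reported as NA",
              call. = FALSE)
    }
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator); reported as NA", call. = FALSE)
    NA_real_
  } else {
    (tp * tn - fp * fn) / mcc_den
  }
  structure(list(accuracy = acc, sensitivity = sn, specificity = sp,
                 mcc = mcc, precision = precision, recall = recall,
                 f1 = f1, auc = NA_real_),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(
    "<metric_set> Acc %.2f%% | Sn %.2f%% | Sp %.2f%% | MCC %.3f | F1 %.3f%s\n",
    x$accuracy, x$sensitivity, x$specificity, x$mcc, x$f1,
    if (is.na(x$auc)) "" else sprintf(" | AUC %.3f", x$auc)))
  invisible(x)
}

metric_fields <- c("accuracy", "sensitivity", "specificity", "mcc",
                   "precision", "recall", "f1", "auc")

#' ROC curve and AUC
#'
#' Threshold-sweep ROC: equal scores are grouped into single threshold steps,
#' and the AUC is the trapezoidal area under the resulting curve (equivalently
#' the Mann-Whitney pair-counting probability with ties counted one half).
#'
#' @param labels binary 0/1 vector with both classes present.
#' @param scores finite numeric scores, higher = more positive.
#' @return list with `curve` (data.frame: threshold, fpr, tpr) and `auc`.
#' @export
roc_curve_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    stop("ROC requires both classes present", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  pos_at <- vapply(thr, function(t) sum(labels == 1L & scores >= t), numeric(1))
  neg_at <- vapply(thr, function(t) sum(labels == 0L & scores >= t), numeric(1))
  curve <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, neg_at / nn),
    tpr = c(0, pos_at / np)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Stratified K-fold assignment
#'
#' Shuffles each class independently (seeded) and deals its members to folds
#' round-robin, so per-fold class ratios stay within one sequence of the
#' global ratio and the test folds partition the data.
#'
#' @param data a `labeled_dataset`.
#' @param folds number of folds, >= 2; every class needs at least `folds`
#'   members.
#' @param seed integer seed. Default 1234.
#' @return list of `folds` elements, each `list(train = indices,
#'   test = indices)`.
#' @export
stratified_kfold <- function(data, folds = 10L, seed = 1234L) {
  stopifnot(inherits(data, "labeled_dataset"), folds >= 2L)
  cc <- class_counts(data)
  if (any(cc < folds)) {
    stop(sprintf("each class needs >= %d members (have %d/%d)",
                 folds, cc[["pos"]], cc[["neg"]]), call. = FALSE)
  }
  assignment <- integer(length(data))
  with_local_seed(seed, {
    for (cls in c(1L, 0L)) {
      idx <- sample(which(data$labels == cls))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  lapply(seq_len(folds), function(f) {
    list(train = which(assignment != f), test = which(assignment == f))
  })
}

#' Classifier adapters for the comparison harness
#'
#' Uniform fit/predict wrappers used by [run_cv]: `"dnn"` is the package's
#' own network; `"nb"`, `"svm"`, `"knn"`, `"rf"`, `"dt"` are thin, non-novel
#' adapters over e1071, class, randomForest and rpart (all in Suggests) for
#' side-by-side comparison tables.
#'
#' @param name one of `"dnn"`, `"nb"`, `"svm"`, `"knn"`, `"rf"`, `"dt"`.
#' @param model_cfg a `dnn_config` (used by `"dnn"` only).
#' @return list with functions `fit(x, y)` and `predict_proba(fit, x)` over
#'   plain numeric matrices.
#' @export
classifier_adapter <- function(name = c("dnn", "nb", "svm", "knn", "rf", "dt"),
                               model_cfg = dnn_config()) {
  name <- match.arg(name)
  need <- function(pkg) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop(sprintf("classifier '%s' requires the suggested package '%s'",
                   name, pkg), call. = FALSE)
    }
  }
  switch(name,
    dnn = list(
      fit = function(x, y) train_dnn(x, y, model_cfg),
      predict_proba = function(fit, x) predict_proba(fit, x)
    ),
    nb = {
      need("e1071")
      list(
        fit = function(x, y) e1071::naiveBayes(x, factor(y, levels = 0:1)),
        predict_proba = function(fit, x)
          stats::predict(fit, x, type = "raw")[, "1"]
      )
    },
    svm = {
      need("e1071")
      list(
        fit = function(x, y) e1071::svm(x, factor(y, levels = 0:1),
                                        probability = TRUE),
        predict_proba = function(fit, x) {
          p <- stats::predict(fit, x, probability = TRUE)
          attr(p, "probabilities")[, "1"]
        }
      )
    },
    knn = {
      need("class")
      list(
        fit = function(x, y) list(x = x, y = factor(y, levels = 0:1)),
        predict_proba = function(fit, x) {
          p <- class::knn(fit$x, x, fit$y, k = 5L, prob = TRUE)
          win <- attr(p, "prob")
          ifelse(p == "1", win, 1 - win)
        }
      )
    },
    rf = {
      need("randomForest")
      list(
        fit = function(x, y)
          randomForest::randomForest(x, factor(y, levels = 0:1)),
        predict_proba = function(fit, x)
          stats::predict(fit, x, type = "prob")[, "1"]
      )
    },
    dt = {
      need("rpart")
      list(
        fit = function(x, y) {
          df <- data.frame(y = factor(y, levels = 0:1), x)
          rpart::rpart(y ~ ., df, method = "class")
        },
        predict_proba = function(fit, x)
          stats::predict(fit, data.frame(x), type = "prob")[, "1"]
      )
    }
  )
}

#' Cross-validated evaluation of the full pipeline
#'
#' For each stratified fold: take the (precomputed, per-sequence) feature
#' rows, fit PCA on the training rows only (when enabled), train the
#' classifier, score the held-out fold and compute metrics including AUC.
#' Encoding is done once up front because every encoder is a pure function of
#' the individual sequence; PCA, the only data-dependent stage, is always
#' refitted inside each fold unless `pca_pooled = TRUE` (a deliberately leaky
#' variant kept for comparison).
#'
#' @param data a `labeled_dataset`.
#' @param encoder_cfg an `encoder_config`.
#' @param use_pca apply PCA feature selection. Default `TRUE`.
#' @param n_components PCA components (default 75).
#' @param model_cfg a `dnn_config` (for the `"dnn"` classifier).
#' @param folds number of CV folds. Default 10.
#' @param seed integer seed for fold assignment. Default 1234.
#' @param only optional single-encoder name for ablation (see
#'   [encode_hybrid]).
#' @param classifier adapter name (see [classifier_adapter]). Default
#'   `"dnn"`.
#' @param pca_pooled fit PCA once on the pooled data instead of per fold
#'   (information-leaking variant; off by default).
#' @param threshold decision threshold. Default 0.5.
#' @return object of class `cv_result`: `per_fold` (list of `metric_set`),
#'   `mean` (`metric_set` of arithmetic per-fold means, `NA` dropped),
#'   `folds`, `seed`, and `pca_models` (per-fold `pca_model`s when PCA is
#'   enabled).
#' @export
run_cv <- function(data, encoder_cfg = encoder_config(), use_pca = TRUE,
                   n_components = 75, model_cfg = dnn_config(),
                   folds = 10L, seed = 1234L, only = NULL,
                   classifier = "dnn", pca_pooled = FALSE, threshold = 0.5) {
  stopifnot(inherits(data, "labeled_dataset"))
  fm <- encode_hybrid(data, encoder_cfg, only = only)
  adapter <- classifier_adapter(classifier, model_cfg)
  assignments <- stratified_kfold(data, folds, seed)
  pooled_pca <- if (use_pca && pca_pooled) fit_pca(fm, n_components) else NULL
  pca_models <- list()
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    fold <- assignments[[f]]
    res <- tryCatch({
      tr <- subset_matrix(fm, fold$train)
      te <- subset_matrix(fm, fold$test)
      if (use_pca) {
        pca <- if (pca_pooled) pooled_pca else fit_pca(tr, n_components)
        pca_models[[f]] <- pca
        tr <- transform_pca(pca, tr)
        te <- transform_pca(pca, te)
      }
      fit <- adapter$fit(tr$values, data$labels[fold$train])
      scores <- adapter$predict_proba(fit, te$values)
      y <- data$labels[fold$test]
      ms <- compute_metrics(confusion(y, classify(scores, threshold)))
      ms$auc <- roc_curve_auc(y, scores)$auc
      ms
    }, error = function(e) {
      stop(sprintf("fold %d/%d: %s", f, folds, conditionMessage(e)),
           call. = FALSE)
    })
    per_fold[[f]] <- res
  }
  structure(list(
    per_fold = per_fold,
    mean = mean_metrics(per_fold),
    folds = as.integer(folds),
    seed = as.integer(seed),
    pca_models = pca_models
  ), class = "cv_result")
}

mean_metrics <- function(per_fold) {
  out <- lapply(metric_fields, function(f) {
    vals <- vapply(per_fold, `[[`, numeric(1), f)
    mean(vals, na.rm = TRUE)
  })
  names(out) <- metric_fields
  structure(out, class = "metric_set")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV (seed %d)\n", x$folds, x$seed))
  print(x$mean)
  invisible(x)
}

#' Per-encoder ablation table
#'
#' Runs [run_cv] once per single encoder, once on the full hybrid vector
#' without PCA, and once with PCA feature selection, and assembles a
#' methods-by-metrics table (the classic ablation layout).
#'
#' @inheritParams run_cv
#' @return data.frame with one row per method and columns
#'   method, accuracy, sensitivity, specificity, f1, mcc, auc.
#' @export
ablation_cv <- function(data, encoder_cfg = encoder_config(),
                        n_components = 75, model_cfg = dnn_config(),
                        folds = 10L, seed = 1234L, classifier = "dnn") {
  encoders <- c("kmer", "rc_kmer", "pse_dnc", "pse_tnc", "tac", "tcc", "dcc")
  runs <- c(
    stats::setNames(lapply(encoders, function(e) list(only = e, pca = FALSE)),
                    encoders),
    list("hybrid" = list(only = NULL, pca = FALSE),
         "hybrid_pca" = list(only = NULL, pca = TRUE))
  )
  rows <- lapply(names(runs), function(nm) {
    r <- runs[[nm]]
    cv <- run_cv(data, encoder_cfg, use_pca = r$pca,
                 n_components = n_components, model_cfg = model_cfg,
                 folds = folds, seed = seed, only = r$only,
                 classifier = classifier)
    data.frame(method = nm,
               accuracy = cv$mean$accuracy,
               sensitivity = cv$mean$sensitivity,
               specificity = cv$mean$specificity,
               f1 = cv$mean$f1,
               mcc = cv$mean$mcc,
               auc = cv$mean$auc)
  })
  do.call(rbind, rows)
}

#' Evaluate a trained model on an independent hold-out set
#'
#' Encodes the independent sequences, projects them through the supplied PCA
#' model (if any), scores them with the trained network and returns a single
#' `metric_set` (with AUC). Warns if any independent id also appears in
#' `train_ids`.
#'
#' @param model a `dnn_model`.
#' @param pca a `pca_model`, or `NULL` when the model was trained on raw
#'   features.
#' @param independent a non-empty `labeled_dataset`.
#' @param encoder_cfg the `encoder_config` used at training time.
#' @param train_ids optional character vector of training ids for the overlap
#'   check.
#' @param threshold decision threshold. Default 0.5.
#' @return a `metric_set`.
#' @export
evaluate_independent <- function(model, pca, independent,
                                 encoder_cfg = encoder_config(),
                                 train_ids = NULL, threshold = 0.5) {
  stopifnot(inherits(model, "dnn_model"))
  if (!inherits(independent, "labeled_dataset") || length(independent) == 0L) {
    stop("independent set must be a non-empty labeled_dataset", call. = FALSE)
  }
  if (!is.null(train_ids)) {
    overlap <- intersect(independent$ids, train_ids)
    if (length(overlap) > 0L) {
      warning(sprintf("independent set shares %d id(s) with training data",
                      length(overlap)), call. = FALSE)
    }
  }
  fm <- encode_hybrid(independent, encoder_cfg)
  if (!is.null(pca)) fm <- transform_pca(pca, fm)
  scores <- predict_proba(model, fm)
  ms <- compute_metrics(confusion(independent$labels,
                                  classify(scores, threshold)))
  if (length(unique(independent$labels)) == 2L) {
    ms$auc <- roc_curve_auc(independent$labels, scores)$auc
  }
  ms
}
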