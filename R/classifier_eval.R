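# Confusion-matrix metrics and criterion-based evaluation of binary
# classifiers. Model fitting is delegated to standard libraries (glm, e1071,
# class, rpart) at documented defaults; this module owns the evaluation
# protocol: stratified k-fold cross-validation with out-of-fold scores, the
# empirical ROC of those scores, and the AIC-ROC / ICOMP-ROC criteria with
# n = number of instances.

#' Confusion counts
#'
#' Cross-tabulates true and predicted 0/1 labels with class 1 as positive.
#'
#' @param truth,estimate 0/1 vectors of equal length.
#' @return A `confusion_counts` list with `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1))
confusion_counts <- function(truth, estimate) {
  if (length(truth) != length(estimate)) {
    stop("truth and estimate must have equal length", call. = FALSE)
  }
  truth <- as.integer(truth)
  estimate <- as.integer(estimate)
  structure(
    list(tp = sum(truth == 1L & estimate == 1L),
         fp = sum(truth == 0L & estimate == 1L),
         tn = sum(truth == 0L & estimate == 0L),
         fn = sum(truth == 1L & estimate == 0L)),
    class = "confusion_counts"
  )
}

#' Metrics from confusion counts
#'
#' Accuracy `(TP+TN)/n`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 `2*precision*recall/(precision+recall)`, error rate `(FP+FN)/n`.
#' Metrics with a zero denominator are reported as `NA` (never coerced to 0)
#' and flagged in the `undefined` column.
#'
#' @param counts A [confusion_counts()].
#' @return One-row tibble of the five metrics plus an `undefined` string.
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$fp + counts$tn + counts$fn
  if (n == 0) stop("no evaluated instances", call. = FALSE)
  undef <- character()
  precision <- if (counts$tp + counts$fp == 0) {
    undef <- c(undef, "precision"); NA_real_
  } else counts$tp / (counts$tp + counts$fp)
  recall <- if (counts$tp + counts$fn == 0) {
    undef <- c(undef, "recall"); NA_real_
  } else counts$tp / (counts$tp + counts$fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    undef <- c(undef, "f1"); NA_real_
  } else 2 * precision * recall / (precision + recall)
  accuracy <- (counts$tp + counts$tn) / n
  tibble::tibble(
    accuracy = accuracy,
    precision = precision,
    recall = recall,
    f1 = f1,
    error_rate = (counts$fp + counts$fn) / n,
    undefined = paste(undef, collapse = ",")
  )
}

#' Supported classifier specifications
#'
#' `"lr"` logistic regression (glm, binomial); `"svm"` e1071 radial SVM with
#' probability output; `"nb"` e1071 naive Bayes; `"knn"` class::knn with
#' `k = 5`; `"dt"` rpart decision tree. All at library defaults.
#'
#' @return Character vector of classifier ids.
#' @export
classifier_specs <- function() c("lr", "svm", "nb", "knn", "dt")

fit_predict_classifier <- function(clf, x_train, y_train, x_test) {
  switch(clf,
    lr = {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, x_train), y_train,
                       family = stats::binomial())
      )
      as.numeric(stats::plogis(cbind(1, x_test) %*% fit$coefficients))
    },
    svm = {
      fit <- e1071::svm(x_train, factor(y_train, levels = c(0, 1)),
                        probability = TRUE)
      pr <- stats::predict(fit, x_test, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    nb = {
      fit <- e1071::naiveBayes(x_train, factor(y_train, levels = c(0, 1)))
      stats::predict(fit, x_test, type = "raw")[, "1"]
    },
    knn = {
      pr <- class::knn(x_train, x_test, factor(y_train, levels = c(0, 1)),
                       k = 5, prob = TRUE)
      p <- attr(pr, "prob")
      ifelse(pr == "1", p, 1 - p)
    },
    dt = {
      df_train <- data.frame(y = factor(y_train, levels = c(0, 1)), x_train)
      fit <- rpart::rpart(y ~ ., df_train, method = "class")
      stats::predict(fit, data.frame(x_test), type = "prob")[, "1"]
    },
    stop("unknown classifier '", clf, "'", call. = FALSE)
  )
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Out-of-fold scores by stratified cross-validation
#'
#' Every instance is scored exactly once by a model not trained on it.
#' Folds are stratified by class; each training fold must contain both
#' classes.
#'
#' @param data Data frame of numeric features plus a 0/1 label column.
#' @param label Label column name (tidy-eval).
#' @param clf One of [classifier_specs()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment (local RNG state).
#' @return Tibble with `row`, `fold`, `truth`, `score`, `estimate` (score
#'   thresholded at 0.5).
#' @export
cv_scores <- function(data, label = label, clf = "lr", k = 5, seed = 1) {
  stopifnot(k >= 2)
  y <- as.integer(dplyr::pull(data, {{ label }}))
  x <- as.matrix(dplyr::select(data, -{{ label }}))
  storage.mode(x) <- "double"
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (min(table(y)) < k) {
    stop("fold count too large for the minority class; use smaller k",
         call. = FALSE)
  }
  fold <- withr::with_seed(seed, stratified_folds(y, k))
  score <- numeric(length(y))
  for (f in seq_len(k)) {
    test <- fold == f
    score[test] <- withr::with_seed(
      seed + f,
      fit_predict_classifier(clf, x[!test, , drop = FALSE], y[!test],
                             x[test, , drop = FALSE])
    )
  }
  tibble::tibble(row = seq_along(y), fold = fold, truth = y, score = score,
                 estimate = as.integer(score >= 0.5))
}

#' Evaluate one classifier on a feature table
#'
#' Runs stratified cross-validation, builds the empirical ROC of the
#' out-of-fold scores, and reports the confusion-matrix metrics (threshold
#' 0.5) together with the trapezoidal AUC and the AIC-ROC / ICOMP-ROC
#' criteria computed from the ROC point-set correlation with `n` equal to the
#' number of instances.
#'
#' @inheritParams cv_scores
#' @param lackfit Passed to the criteria.
#' @return One-row tibble (`classifier`, five metrics, `auc`, `aic_roc`,
#'   `icomp_roc`, `c1`, `r`, `n`).
#' @export
#' @examples
#' \donttest{
#' tbl <- simulate_feature_table(n_instances = 120, n_features = 5,
#'                               n_informative = 2, effect_size = 1.5, seed = 1)
#' evaluate_classifier(tbl, label = label, clf = "lr", seed = 1)
#' }
evaluate_classifier <- function(data, label = label, clf = "lr", k = 5,
                                seed = 1, lackfit = "standard") {
  oof <- cv_scores(data, {{ label }}, clf = clf, k = k, seed = seed)
  counts <- confusion_counts(oof$truth, oof$estimate)
  metrics <- confusion_metrics(counts)
  curve <- roc_empirical_vec(oof$score, oof$truth)
  rep <- score_candidate(curve, n = nrow(oof), lackfit = lackfit,
                         candidate = clf)
  dplyr::bind_cols(
    tibble::tibble(classifier = clf),
    dplyr::select(metrics, -"undefined"),
    dplyr::select(rep, "auc", "aic_roc", "icomp_roc", "c1", "r", "n"),
    dplyr::select(metrics, "undefined")
  )
}

#' Evaluate a portfolio of classifiers
#'
#' @inheritParams evaluate_classifier
#' @param clfs Classifier ids; defaults to all of [classifier_specs()].
#' @return Tibble with one row per classifier.
#' @export
evaluate_classifiers <- function(data, label = label,
                                 clfs = classifier_specs(), k = 5, seed = 1,
                                 lackfit = "standard") {
  purrr::map_dfr(clfs, function(clf) {
    evaluate_classifier(data, {{ label }}, clf = clf, k = k, seed = seed,
                        lackfit = lackfit)
  })
}
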