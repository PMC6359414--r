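#' Train/test split of a cohort table
#'
#' Seeded, optionally class-stratified partition of a labelled feature
#' table into a training and a test set (default 70 % / 30 %, the usual
#' protocol for this kind of screening model).
#'
#' @param cohort `data.frame` with a `label` column; both classes must
#'   be present with at least 2 rows each.
#' @param train_fraction fraction of rows assigned to training, in
#'   (0, 1); default 0.7.
#' @param stratified preserve class proportions in both parts (default
#'   TRUE).
#' @param seed integer seed; the same seed reproduces the partition.
#' @return List with `train` and `test` data frames (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(cohort, train_fraction = 0.7, stratified = TRUE,
                         seed = 1L) {
  stopifnot(is.data.frame(cohort), "label" %in% names(cohort))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("'train_fraction' must lie in (0, 1)", call. = FALSE)
  }
  lab <- as.character(cohort$label)
  if (length(unique(lab)) < 2) {
    stop("both classes must be present in the cohort", call. = FALSE)
  }
  if (any(table(lab) < 2)) {
    stop("at least 2 rows per class required", call. = FALSE)
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  if (stratified) {
    train_idx <- integer(0)
    for (lv in unique(lab)) {
      idx <- which(lab == lv)
      k <- round(train_fraction * length(idx))
      k <- min(max(k, 1L), length(idx) - 1L)
      train_idx <- c(train_idx, sample(idx, k))
    }
  } else {
    k <- round(train_fraction * n)
    train_idx <- sample(n, min(max(k, 1L), n - 1L))
  }
  list(train = cohort[sort(train_idx), , drop = FALSE],
       test = cohort[sort(setdiff(seq_len(n), train_idx)), , drop = FALSE])
}

# feature matrix used for modelling: numeric columns minus identifiers
.model_matrix <- function(df, feature_cols = NULL) {
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(df)[vapply(df, is.numeric, TRUE)],
                            c("label"))
  }
  as.matrix(df[, feature_cols, drop = FALSE])
}

.check_classes <- function(lab) {
  lv <- unique(lab)
  if (length(lv) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  lv
}

#' Random-forest classifier for hypertension screening
#'
#' Ensemble of `n_trees` fully grown binary classification trees, each
#' trained on a bootstrap sample of the training rows; at every node a
#' fresh random subset of `mtry` features is searched for the best
#' split, scored either by the Gini index (CART-style) or by the
#' information-gain/entropy criterion (ID3-style). Classification is by
#' majority vote across trees; the predicted probability of the
#' positive class is the fraction of trees voting for it, which doubles
#' as the patient feedback value. The weighted impurity decrease of
#' every split is accumulated per feature for mean-decrease-impurity
#' importance ([feature_importance()]).
#'
#' The trees are grown by the package itself (rather than delegated to
#' an existing forest implementation) so that both split criteria are
#' available under one interface and the impurity bookkeeping matches
#' the importance definition exactly.
#'
#' @param train labelled training `data.frame` (a `label` column plus
#'   numeric features).
#' @param n_trees number of trees; default 500.
#' @param criterion split metric: `"gini"` or `"entropy"`.
#' @param mtry features per tree; default `floor(sqrt(p))`.
#' @param positive label of the positive (hypertensive) class; default
#'   `"hypertensive"`, falling back to the second class level.
#' @param feature_cols explicit feature columns; defaults to all numeric
#'   columns except `label`.
#' @param seed integer seed controlling bootstrap and feature sampling.
#' @return An object of class `c("crowdhrv_rf", "hrv_classifier")`.
#' @seealso [predict_proba()], [evaluate_model()], [feature_importance()]
#' @export
train_rf <- function(train, n_trees = 500, criterion = c("gini", "entropy"),
                     mtry = NULL, positive = NULL, feature_cols = NULL,
                     seed = 1L) {
  criterion <- match.arg(criterion)
  stopifnot(is.data.frame(train), "label" %in% names(train))
  lab <- as.character(train$label)
  lv <- .check_classes(lab)
  positive <- .resolve_positive(positive, lv)
  X <- .model_matrix(train, feature_cols)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; lab <- lab[keep]
  .check_classes(lab)
  p <- ncol(X); n <- nrow(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- min(as.integer(mtry), p)

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  y01 <- as.integer(lab == positive)
  imp <- setNames(numeric(p), colnames(X))
  trees <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    rows <- sample(n, n, replace = TRUE)
    tree <- .grow_tree(X[rows, , drop = FALSE], y01[rows], mtry = mtry,
                       criterion = criterion)
    imp <- imp + tree$importance
    tree$importance <- NULL
    trees[[b]] <- tree
  }
  structure(list(kind = "random_forest", trees = trees,
                 feature_cols = colnames(X),
                 classes = c(setdiff(lv, positive)[1], positive),
                 positive = positive, criterion = criterion,
                 mtry = mtry, n_trees = n_trees,
                 importance_raw = imp,
                 medians = apply(X, 2, median), seed = as.integer(seed)),
            class = c("crowdhrv_rf", "hrv_classifier"))
}

.resolve_positive <- function(positive, lv) {
  if (!is.null(positive)) {
    if (!positive %in% lv) stop("positive class '", positive,
                                "' not present", call. = FALSE)
    return(positive)
  }
  if ("hypertensive" %in% lv) "hypertensive" else lv[length(lv)]
}

#' Multi-layer-perceptron classifier
#'
#' One-hidden-layer sigmoid network trained on range-normalised
#' features. Unlike the tree ensemble, an MLP requires its inputs on a
#' common scale, so per-feature min--max normalisation to [0, 1] is
#' fitted on the training data only, stored with the model, and applied
#' (clipped to [0, 1]) at prediction time. The network is fitted with
#' \pkg{nnet} by minimising the cross-entropy of the sigmoid output;
#' the seeded weight initialisation makes training reproducible.
#'
#' @param train labelled training `data.frame`.
#' @param hidden_units hidden-layer size; default 16.
#' @param epochs maximum optimisation iterations; default 500.
#' @param positive,feature_cols,seed as in [train_rf()].
#' @return An object of class `c("crowdhrv_mlp", "hrv_classifier")`.
#' @export
train_mlp <- function(train, hidden_units = 16, epochs = 500,
                      positive = NULL, feature_cols = NULL, seed = 1L) {
  stopifnot(is.data.frame(train), "label" %in% names(train))
  lab <- as.character(train$label)
  lv <- .check_classes(lab)
  positive <- .resolve_positive(positive, lv)
  X <- .model_matrix(train, feature_cols)
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; lab <- lab[keep]
  .check_classes(lab)

  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1  # constant feature maps to 0.5
  Xn <- sweep(sweep(X, 2, rng[1, ]), 2, span, "/")
  Xn[, span == 1 & rng[1, ] == rng[2, ]] <- 0.5

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  y <- as.numeric(lab == positive)
  fit <- nnet::nnet(x = Xn, y = y, size = as.integer(hidden_units),
                    entropy = TRUE, maxit = as.integer(epochs),
                    decay = 0, trace = FALSE, rang = 0.5,
                    MaxNWts = 100000)
  if (!is.finite(fit$value)) {
    stop("MLP training diverged (non-finite loss)", call. = FALSE)
  }
  structure(list(kind = "mlp", fit = fit, feature_cols = colnames(X),
                 classes = c(setdiff(lv, positive)[1], positive),
                 positive = positive, norm_min = rng[1, ], norm_span = span,
                 hidden_units = hidden_units, epochs = epochs,
                 medians = apply(X, 2, median), seed = as.integer(seed)),
            class = c("crowdhrv_mlp", "hrv_classifier"))
}

#' Predicted probability of the hypertensive (positive) class
#'
#' Returns, for each row of `newdata`, the model's probability that the
#' record belongs to a subject in the hypertensive state -- the number
#' fed back to the patient. Classification uses a decision threshold
#' (default 0.5); probabilities in the warning band just below the
#' threshold can be surfaced as "high risk" via [classify_feedback()].
#'
#' @param model a fitted `hrv_classifier`.
#' @param newdata `data.frame` containing the model's feature columns.
#' @param impute replace missing feature values by the training-set
#'   medians stored in the model (default FALSE: missing features are
#'   an error listing the offending fields).
#' @return Numeric vector of probabilities in [0, 1].
#' @export
predict_proba <- function(model, newdata, impute = FALSE) {
  stopifnot(inherits(model, "hrv_classifier"))
  missing_cols <- setdiff(model$feature_cols, names(newdata))
  if (length(missing_cols) > 0) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(newdata[, model$feature_cols, drop = FALSE])
  if (anyNA(X)) {
    if (!impute) {
      bad <- colnames(X)[colSums(is.na(X)) > 0]
      stop("missing feature value(s) in: ", paste(bad, collapse = ", "),
           "; set impute = TRUE to use training medians", call. = FALSE)
    }
    for (j in seq_len(ncol(X))) {
      X[is.na(X[, j]), j] <- model$medians[j]
    }
  }
  if (inherits(model, "crowdhrv_rf")) {
    votes <- numeric(nrow(X))
    for (tree in model$trees) {
      votes <- votes + as.numeric(.predict_tree(tree, X) >= 0.5)
    }
    votes / length(model$trees)
  } else {
    Xn <- sweep(sweep(X, 2, model$norm_min), 2, model$norm_span, "/")
    Xn <- pmin(pmax(Xn, 0), 1)  # clip outside the training range
    as.numeric(predict(model$fit, Xn, type = "raw"))
  }
}

#' @export
predict.hrv_classifier <- function(object, newdata,
                                   type = c("prob", "class"),
                                   threshold = 0.5, ...) {
  type <- match.arg(type)
  pr <- predict_proba(object, newdata, ...)
  if (type == "prob") pr else
    ifelse(pr >= threshold, object$positive,
           setdiff(object$classes, object$positive)[1])
}

#' Patient feedback from a predicted probability
#'
#' Maps the probability of the hypertensive state to a status string:
#' `"positive"` at or above the decision threshold, `"negative
#' (high risk)"` inside the warning band just below it, `"negative"`
#' otherwise. A feedback of e.g. 0.353 with the defaults is currently
#' negative but flagged as high risk, suggesting the subject reduce
#' activity.
#'
#' @param prob probability (or vector of probabilities) in [0, 1].
#' @param threshold decision threshold; default 0.5.
#' @param warn_band lower/upper edge of the high-risk band; default
#'   `c(0.3, 0.5)`.
#' @return Character vector of status strings.
#' @export
classify_feedback <- function(prob, threshold = 0.5,
                              warn_band = c(0.3, 0.5)) {
  stopifnot(all(prob >= 0 & prob <= 1, na.rm = TRUE))
  ifelse(prob >= threshold, "positive",
         ifelse(prob >= warn_band[1] & prob < warn_band[2],
                "negative (high risk)", "negative"))
}

#' Classification metrics from a confusion matrix
#'
#' The five standard screening metrics in percent: accuracy
#' `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
#' positive prediction `TP/(TP+FP)` and negative prediction
#' `TN/(TN+FN)`. Undefined ratios (zero denominator) are `NA`.
#'
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @return Named list of the five metrics, in percent.
#' @examples
#' confusion_metrics(tp = 8, fp = 2, tn = 6, fn = 4)$accuracy  # 70
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  list(accuracy = pct(tp + tn, tp + tn + fp + fn),
       sensitivity = pct(tp, tp + fn),
       specificity = pct(tn, tn + fp),
       positive_prediction = pct(tp, tp + fp),
       negative_prediction = pct(tn, tn + fn))
}

#' Evaluate a classifier on a test set
#'
#' Confusion matrix at the decision threshold, the five
#' [confusion_metrics()] in percent, the ROC curve obtained by sweeping
#' the threshold over the predicted probabilities, and its area under
#' the curve by the trapezoid rule. With a single-class test set the
#' defined metrics are still reported and AUC is `NA`.
#'
#' @param model fitted `hrv_classifier`.
#' @param test labelled test `data.frame`.
#' @param threshold decision threshold; default 0.5.
#' @param impute passed to [predict_proba()].
#' @return An `eval_report`: list with `confusion` (tn, fp, fn, tp),
#'   `metrics`, `roc` (data.frame fpr/tpr/threshold), `auc`, and the raw
#'   `probabilities`.
#' @export
evaluate_model <- function(model, test, threshold = 0.5, impute = FALSE) {
  stopifnot(is.data.frame(test), "label" %in% names(test), nrow(test) > 0)
  pr <- predict_proba(model, test, impute = impute)
  truth <- as.character(test$label) == model$positive
  keep <- !is.na(pr)
  pr <- pr[keep]; truth <- truth[keep]
  pred <- pr >= threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  metrics <- confusion_metrics(tp, fp, tn, fn)

  roc <- roc_points(pr, truth)
  auc <- if (any(truth) && any(!truth)) trapezoid_auc(roc) else NA_real_
  structure(list(confusion = c(tn = tn, fp = fp, fn = fn, tp = tp),
                 metrics = metrics, roc = roc, auc = auc,
                 threshold = threshold, probabilities = pr),
            class = "eval_report")
}

# ROC curve by threshold sweep (thresholds at every distinct probability)
roc_points <- function(prob, truth) {
  th <- c(Inf, sort(unique(prob), decreasing = TRUE))
  pos <- sum(truth); neg <- sum(!truth)
  tpr <- vapply(th, function(t) if (pos > 0) sum(prob >= t & truth) / pos
                else NA_real_, 0)
  fpr <- vapply(th, function(t) if (neg > 0) sum(prob >= t & !truth) / neg
                else NA_real_, 0)
  data.frame(threshold = th, fpr = fpr, tpr = tpr)
}

trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  x <- c(roc$fpr[o], 1); y <- c(roc$tpr[o], 1)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Classification performance [%]\n")
  m <- x$metrics
  cat(sprintf("  Accuracy %.1f  Sensitivity %.1f  Specificity %.1f",
              m$accuracy, m$sensitivity, m$specificity))
  cat(sprintf("  Positive Prediction %.1f  Negative Prediction %.1f\n",
              m$positive_prediction, m$negative_prediction))
  cc <- x$confusion
  cat(sprintf("  confusion: TN=%d FP=%d FN=%d TP=%d; AUC = %s\n",
              cc["tn"], cc["fp"], cc["fn"], cc["tp"],
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}

#' Mean-decrease-impurity feature importance
#'
#' For a random forest, the impurity decrease of every split is
#' attributed to its splitting feature, summed within each tree and
#' averaged across the forest; the result is normalised to sum to 1.
#' Features never selected for a split get weight 0.
#'
#' @param model a `crowdhrv_rf` model; MLP models are not supported
#'   (importance is not defined for them here).
#' @return Named numeric vector (one weight per feature, non-negative,
#'   summing to 1), sorted decreasing.
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "crowdhrv_rf")) {
    stop("feature importance is only available for random-forest models",
         call. = FALSE)
  }
  imp <- model$importance_raw
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  sort(imp, decreasing = TRUE)
}
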