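#' Specification of a motion-sickness classifier
#'
#' The four classical learners evaluated on the (mPD, sPD, PRC) feature
#' triple. Defaults carry the tuned hyperparameters of the study setup:
#' data standardization for LDA and both SVMs, box constraint (the SVM
#' cost parameter C) 7.7 for the linear kernel and 0.09 for the RBF
#' kernel, and a decision tree limited to 4 splits grown by maximum
#' deviance (information) reduction.
#'
#' @param kind One of `"lda"`, `"tree"`, `"svm_linear"`, `"svm_rbf"`.
#' @param standardize Standardize features (training-set statistics only)?
#'   Defaults to `TRUE` except for the tree.
#' @param box_constraint SVM cost C; defaults 7.7 (linear) / 0.09 (RBF).
#' @param rbf_gamma RBF kernel scale; default `1 / n_features` on the
#'   standardized features.
#' @param tree_max_splits Maximum number of splits of the decision tree.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "svm_linear", "lda", "tree"),
                            standardize = NULL, box_constraint = NULL,
                            rbf_gamma = NULL, tree_max_splits = 4) {
  kind <- match.arg(kind)
  standardize <- standardize %||% (kind != "tree")
  box_constraint <- box_constraint %||%
    switch(kind, svm_linear = 7.7, svm_rbf = 0.09, NA_real_)
  if (!is.na(box_constraint) && box_constraint <= 0) {
    abort("`box_constraint` must be positive.")
  }
  structure(list(kind = kind, standardize = standardize,
                 box_constraint = box_constraint, rbf_gamma = rbf_gamma,
                 tree_max_splits = tree_max_splits),
            class = "classifier_spec")
}

check_feature_data <- function(data, features, label) {
  missing_cols <- setdiff(c(features, label), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing columns: ", paste(missing_cols, collapse = ", "), "."))
  }
  if (anyNA(data[, c(features, label)])) {
    abort("Feature matrix contains missing values.")
  }
  invisible(data)
}

#' Fit a motion-sickness classifier
#'
#' Trains one of the four learners on a feature table. Standardization
#' statistics (mean/sd per feature) are estimated on the training rows
#' only and stored in the model so held-out data is transformed with
#' frozen parameters.
#'
#' @param data Data frame with the feature columns and a two-level label
#'   column.
#' @param spec A [classifier_spec()].
#' @param features Character vector of feature column names.
#' @param label Name of the label column.
#' @param positive Level treated as the positive (motion-sickness) class.
#' @param seed RNG seed (fitting is deterministic; the seed shields
#'   against any library-internal randomness).
#' @return An object of class `ms_model`.
#' @examples
#' co <- simulate_cohort(6, "strong", duration = 60, seed = 1)
#' post <- dplyr::filter(co, phase == "post")
#' fit <- fit_classifier(post, classifier_spec("lda"))
#' predict(fit, post)
#' @export
fit_classifier <- function(data, spec = classifier_spec(),
                           features = c("mPD", "sPD", "prc"),
                           label = "condition", positive = "HMD",
                           seed = NULL) {
  check_feature_data(data, features, label)
  y <- as.character(data[[label]])
  lev <- unique(y)
  if (length(lev) < 2) abort("Training data must contain both classes.")
  if (!positive %in% lev) abort(sprintf("Positive class '%s' absent.", positive))
  negative <- setdiff(lev, positive)[[1]]
  yf <- factor(y, levels = c(negative, positive))
  x <- as.matrix(data[, features])

  ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (spec$standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0] <- 1
  }
  xs <- scale(x, center = ctr, scale = scl)

  fit <- local_seed(seed, switch(
    spec$kind,
    lda = MASS::lda(xs, grouping = yf),
    tree = {
      df <- data.frame(.y = yf, xs)
      full <- rpart::rpart(.y ~ ., data = df, method = "class",
                           parms = list(split = "information"),
                           control = rpart::rpart.control(
                             minsplit = 2, minbucket = 1, cp = 0, xval = 0))
      cpt <- full$cptable
      ok <- cpt[cpt[, "nsplit"] <= spec$tree_max_splits, , drop = FALSE]
      rpart::prune(full, cp = ok[nrow(ok), "CP"])
    },
    svm_linear = e1071::svm(xs, yf, kernel = "linear",
                            cost = spec$box_constraint, scale = FALSE),
    svm_rbf = e1071::svm(xs, yf, kernel = "radial",
                         cost = spec$box_constraint,
                         gamma = spec$rbf_gamma %||% (1 / ncol(xs)),
                         scale = FALSE)
  ))

  model <- structure(list(spec = spec, fit = fit, features = features,
                          label = label, positive = positive,
                          negative = negative, center = ctr, scale = scl,
                          score_flip = FALSE, n_train = nrow(data)),
                     class = "ms_model")
  # orient raw decision scores so larger = more motion-sickness-like
  sc <- model_scores(model, xs)
  if (mean(sc[yf == positive]) < mean(sc[yf == negative])) {
    model$score_flip <- TRUE
  }
  model
}

# continuous decision score on (already standardized) feature matrix
model_scores <- function(model, xs) {
  s <- switch(
    model$spec$kind,
    lda = predict(model$fit, xs)$posterior[, model$positive],
    tree = predict(model$fit, data.frame(xs), type = "prob")[, model$positive],
    {
      dv <- attr(predict(model$fit, xs, decision.values = TRUE),
                 "decision.values")
      as.numeric(dv[, 1])
    })
  if (isTRUE(model$score_flip)) -s else s
}

#' Predict from a fitted motion-sickness classifier
#'
#' @param object An `ms_model`.
#' @param newdata Data frame containing the model's feature columns.
#' @param type `"label"` for class labels, `"score"` for continuous
#'   decision values (larger = more sickness-like).
#' @param ... Unused.
#' @return Character vector of labels or numeric scores.
#' @export
predict.ms_model <- function(object, newdata, type = c("label", "score"), ...) {
  type <- match.arg(type)
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("Feature mismatch; missing: ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  x <- as.matrix(newdata[, object$features])
  xs <- scale(x, center = object$center, scale = object$scale)
  if (type == "score") return(model_scores(object, xs))
  lab <- switch(
    object$spec$kind,
    lda = as.character(predict(object$fit, xs)$class),
    tree = as.character(predict(object$fit, data.frame(xs), type = "class")),
    as.character(predict(object$fit, xs)))
  lab
}

#' @export
print.ms_model <- function(x, ...) {
  cat(sprintf("<ms_model %s: %s vs %s, features %s, n = %d>\n",
              x$spec$kind, x$positive, x$negative,
              paste(x$features, collapse = "/"), x$n_train))
  invisible(x)
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + FN + TN + FP)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`, with
#' positives = motion-sickness (HMD) sessions. Undefined ratios (empty
#' class) are `NA`.
#'
#' @param tp,fn,tn,fp Non-negative confusion counts.
#' @return One-row tibble `(TP, FN, TN, FP, accuracy, sensitivity,
#'   specificity)`.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || sum(counts) == 0) {
    abort("Counts must be non-negative with a positive total.")
  }
  tibble::tibble(
    TP = tp, FN = fn, TN = tn, FP = fp,
    accuracy = (tp + tn) / sum(counts),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps the decision threshold over the distinct score values (ties step
#' simultaneously) and integrates the ROC curve by the trapezoidal rule.
#'
#' @param scores Numeric decision values, larger = more positive-like.
#' @param labels Vector of class labels.
#' @param positive Positive-class label.
#' @return List with `roc`, a tibble `(threshold, fpr, tpr)`, and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "HMD") {
  is_pos <- labels == positive
  P <- sum(is_pos); N <- sum(!is_pos)
  if (P == 0 || N == 0) abort("Both classes must be present for a ROC curve.")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & is_pos) / P, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !is_pos) / N, 0)
  roc <- tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr),
                        tpr = c(0, tpr))
  if (tail(roc$fpr, 1) < 1 || tail(roc$tpr, 1) < 1) {
    roc <- dplyr::bind_rows(roc, tibble::tibble(threshold = -Inf,
                                                fpr = 1, tpr = 1))
  }
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

new_ms_eval <- function(kind, split, truth, pred, scores, labels_pos, n_folds = NA) {
  tp <- sum(pred == labels_pos & truth == labels_pos)
  fn <- sum(pred != labels_pos & truth == labels_pos)
  tn <- sum(pred != labels_pos & truth != labels_pos)
  fp <- sum(pred == labels_pos & truth != labels_pos)
  cm <- confusion_metrics(tp, fn, tn, fp)
  ra <- roc_auc(scores, truth, positive = labels_pos)
  out <- dplyr::bind_cols(
    tibble::tibble(classifier = kind, split = split, n = length(truth)),
    cm, tibble::tibble(auc = ra$auc))
  attr(out, "roc") <- ra$roc
  attr(out, "scores") <- tibble::tibble(truth = truth, score = scores)
  class(out) <- c("ms_eval", class(out))
  out
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Splits rows into stratified folds (seeded), fits the classifier on each
#' training partition — including its standardization statistics, so no
#' information leaks from the held-out fold — and pools the held-out
#' predictions into a single confusion matrix and a pooled-score ROC/AUC.
#'
#' @inheritParams fit_classifier
#' @param folds Number of folds (default 10).
#' @return A one-row tibble of class `ms_eval` with `TP, FN, TN, FP,
#'   accuracy, sensitivity, specificity, auc`; the ROC points and pooled
#'   scores are attached as attributes.
#' @export
crossval_classifier <- function(data, spec = classifier_spec(),
                                features = c("mPD", "sPD", "prc"),
                                label = "condition", positive = "HMD",
                                folds = 10, seed = 1) {
  check_feature_data(data, features, label)
  n <- nrow(data)
  if (n < folds) abort("Fewer rows than folds.")
  y <- as.character(data[[label]])
  fold_id <- integer(n)
  local_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  pred <- character(n); sc <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- data[fold_id != f, , drop = FALSE]
    te <- data[fold_id == f, , drop = FALSE]
    if (nrow(te) == 0) next
    m <- fit_classifier(tr, spec, features, label, positive, seed = seed)
    pred[fold_id == f] <- predict(m, te, type = "label")
    sc[fold_id == f] <- predict(m, te, type = "score")
  }
  new_ms_eval(spec$kind, "cv", y, pred, sc, positive, n_folds = folds)
}

#' Evaluate a fitted classifier on held-out data
#'
#' Applies the frozen model (including its frozen standardization) to
#' unseen rows and reports the full confusion-matrix metrics and AUC.
#'
#' @param model A fitted `ms_model`.
#' @param data Held-out feature table with the same feature and label
#'   columns.
#' @return A one-row `ms_eval` tibble (see [crossval_classifier()]).
#' @export
evaluate_holdout <- function(model, data) {
  if (nrow(data) == 0) abort("Held-out data is empty.")
  check_feature_data(data, model$features, model$label)
  truth <- as.character(data[[model$label]])
  new_ms_eval(model$spec$kind, "holdout", truth,
              predict(model, data, type = "label"),
              predict(model, data, type = "score"), model$positive)
}
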