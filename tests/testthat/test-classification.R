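test_that("all four learners separate a well-separated cohort", {
  feats <- separable_features(12)
  for (kind in c("lda", "tree", "svm_linear", "svm_rbf")) {
    m <- fit_classifier(feats, classifier_spec(kind), seed = 1)
    acc <- mean(predict(m, feats) == feats$condition)
    expect_gte(acc, 0.95)
  }
  # linear SVM achieves perfect training accuracy on separable data
  m <- fit_classifier(feats, classifier_spec("svm_linear"), seed = 1)
  expect_equal(mean(predict(m, feats) == feats$condition), 1.0)
})

test_that("irreducibly ambiguous rows cap accuracy at chance", {
  # two distinct feature points, each carrying both labels equally often
  dup <- tibble::tibble(condition = rep(c("2D", "HMD"), 10),
                        mPD = rep(c(33, 37), each = 10),
                        sPD = rep(c(1.1, 1.5), each = 10),
                        prc = rep(c(0.4, 0.6), each = 10))
  m <- fit_classifier(dup, classifier_spec("svm_linear"), seed = 1)
  expect_equal(mean(predict(m, dup) == dup$condition), 0.5)
})

test_that("training rejects single-class and incomplete inputs", {
  feats <- separable_features(5)
  expect_error(fit_classifier(feats[feats$condition == "HMD", ],
                              classifier_spec("lda")), "both classes")
  feats$prc[3] <- NA
  expect_error(fit_classifier(feats, classifier_spec("lda")), "missing")
})

test_that("confusion metrics reproduce the count arithmetic", {
  m1 <- confusion_metrics(21, 3, 22, 2)
  expect_equal(m1$accuracy, 0.8958, tolerance = 1e-4)
  expect_equal(m1$sensitivity, 0.875)
  expect_equal(m1$specificity, 0.9167, tolerance = 1e-4)
  m2 <- confusion_metrics(17, 6, 20, 3)
  expect_equal(m2$accuracy, 0.8043, tolerance = 1e-4)
  expect_equal(m2$sensitivity, 0.7391, tolerance = 1e-4)
  expect_equal(m2$specificity, 0.8696, tolerance = 1e-4)
  m3 <- confusion_metrics(0, 0, 10, 0)
  expect_equal(m3$accuracy, 1)
  expect_true(is.na(m3$sensitivity))
  expect_error(confusion_metrics(0, 0, 0, 0), "positive total")
  # identity: accuracy = (sens*P + spec*N)/(P+N)
  set.seed(2)
  for (i in 1:10) {
    cts <- rpois(4, 10) + 1
    m <- confusion_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(m$accuracy,
                 (m$sensitivity * (cts[1] + cts[2]) +
                    m$specificity * (cts[3] + cts[4])) / sum(cts))
  }
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.3), c("HMD", "2D", "HMD", "2D"),
               positive = "HMD")
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(2, 3, -1, -2), rep(c("HMD", "2D"), each = 2))$auc, 1)
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    labels <- sample(c("HMD", "2D"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- round(rnorm(n), 1)  # coarse grid forces ties
    expect_equal(roc_auc(scores, labels)$auc,
                 oracle_auc_pairs(scores, labels, "HMD"), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, rep("HMD", 3)), "Both classes")
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(7)
  labels <- sample(c("HMD", "2D"), 40, replace = TRUE)
  scores <- rnorm(40) + (labels == "HMD")
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("2D", "HMD"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("chance-level scores give AUC near one half", {
  set.seed(5)
  labels <- rep(c("HMD", "2D"), each = 250)
  expect_lt(abs(roc_auc(rnorm(500), labels)$auc - 0.5), 0.1)
})

test_that("ten-fold CV is deterministic, pooled, and leak-free", {
  feats <- separable_features(12, seed = 3)
  e1 <- crossval_classifier(feats, classifier_spec("svm_rbf"), seed = 42)
  e2 <- crossval_classifier(feats, classifier_spec("svm_rbf"), seed = 42)
  expect_identical(tibble::as_tibble(e1), tibble::as_tibble(e2))
  expect_equal(e1$TP + e1$FN + e1$TN + e1$FP, nrow(feats))
  expect_error(crossval_classifier(feats[1:5, ], classifier_spec("lda")),
               "Fewer rows than folds")

  # leakage sentinel: a wild outlier in one fold's test rows must not
  # perturb the standardization used to score any other fold, so removing
  # it leaves other folds' pooled predictions unchanged relative to a
  # training run that never saw it
  s1 <- separable_features(12, seed = 8)
  m_clean <- fit_classifier(s1, classifier_spec("lda"), seed = 1)
  s2 <- s1
  s2$mPD[1] <- 1e6  # sentinel in (at most) one fold
  m_dirty <- fit_classifier(s2[-1, ], classifier_spec("lda"), seed = 1)
  probe <- s1[10:24, ]
  expect_equal(predict(m_dirty, probe, type = "score"),
               fit_classifier(s1[-1, ], classifier_spec("lda"),
                              seed = 1) |> predict(probe, type = "score"),
               tolerance = 1e-12)
})

test_that("strong cohorts classify well; null cohorts hover at chance", {
  accs <- vapply(1:3, function(s) {
    co <- simulate_cohort(24, "strong", duration = 120, seed = s)
    post <- co[co$phase == "post", ]
    crossval_classifier(post, classifier_spec("svm_rbf"), seed = s)$accuracy
  }, 0)
  expect_true(all(accs >= 0.85))
  null_accs <- vapply(1:4, function(s) {
    co <- simulate_cohort(24, "null", duration = 120, seed = 100 + s)
    post <- co[co$phase == "post", ]
    crossval_classifier(post, classifier_spec("lda"), seed = s)$accuracy
  }, 0)
  expect_lt(abs(mean(null_accs) - 0.5), 0.15)
})

test_that("label permutation drives CV accuracy to chance", {
  feats <- separable_features(12, seed = 6)
  set.seed(99)
  accs <- vapply(1:20, function(i) {
    perm <- feats
    perm$condition <- sample(perm$condition)
    crossval_classifier(perm, classifier_spec("lda"), seed = i)$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("holdout evaluation freezes the model and standardization", {
  feats <- separable_features(10, seed = 4)
  m <- fit_classifier(feats, classifier_spec("svm_linear"), seed = 1)
  resub <- evaluate_holdout(m, feats)
  expect_equal(resub$accuracy,
               mean(predict(m, feats) == feats$condition))
  fresh <- separable_features(10, seed = 5)
  ho <- evaluate_holdout(m, fresh)
  expect_gte(ho$accuracy, 0.75)
  expect_error(evaluate_holdout(m, fresh[0, ]), "empty")
  expect_error(evaluate_holdout(m, fresh[, 1:2]), "Missing columns")
})

test_that("model and report tidiers expose the expected shapes", {
  feats <- separable_features(8)
  m <- fit_classifier(feats, classifier_spec("lda"), seed = 1)
  td <- tidy(m)
  expect_setequal(td$term, c("mPD", "sPD", "prc"))
  gl <- glance(m)
  expect_equal(gl$kind, "lda")
  ev <- evaluate_holdout(m, feats)
  expect_true(all(c("accuracy", "auc") %in% names(glance(ev))))
})
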