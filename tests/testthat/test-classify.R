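test_that("confusion-matrix metrics match hand arithmetic", {
  perfect <- metrics_from_confusion(list(tp = 50, tn = 50, fp = 0, fn = 0))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f1, 1)

  m <- metrics_from_confusion(list(tp = 45, fp = 5, fn = 3, tn = 47))
  expect_equal(m$accuracy, 0.92)
  expect_equal(m$precision, 0.90)
  expect_equal(m$recall, 0.9375)
  expect_equal(m$f1, 0.9184, tolerance = 1e-4)

  deg <- metrics_from_confusion(list(tp = 0, fp = 0, fn = 10, tn = 90))
  expect_equal(deg$precision, 0)
  expect_true("precision" %in% deg$undefined)

  # invariant under scaling all counts
  m4 <- metrics_from_confusion(list(tp = 180, fp = 20, fn = 12, tn = 188))
  expect_equal(m4[c("accuracy", "precision", "recall", "f1")],
               m[c("accuracy", "precision", "recall", "f1")])
})

test_that("rank-statistic AUC honors the standard conventions", {
  y <- c(0, 0, 1, 1)
  expect_equal(auc_rank(c(0.1, 0.2, 0.8, 0.9), y), 1)
  expect_equal(auc_rank(c(0.9, 0.8, 0.2, 0.1), y), 0)
  expect_equal(auc_rank(rep(0.5, 4), y), 0.5)
  set.seed(2)
  s <- rnorm(100); yy <- rep(c(0, 1), 50)
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(auc_rank(s, yy),
                 as.numeric(pROC::auc(pROC::roc(yy, s, quiet = TRUE,
                                                levels = c(0, 1),
                                                direction = "<"))))
  }
})

test_that("stratified folds partition the data with even class balance", {
  y <- rep(c(0L, 1L), each = 50)
  folds <- stratified_folds(y, k = 10, seed = 1)
  expect_setequal(unique(folds), 1:10)
  for (f in 1:10) {
    expect_equal(sum(folds == f & y == 0), 5)
    expect_equal(sum(folds == f & y == 1), 5)
  }
  # uneven classes: per-fold counts within 1 of exact proportion
  y2 <- rep(c(0L, 1L), c(53, 47))
  f2 <- stratified_folds(y2, k = 10, seed = 2)
  expect_equal(sort(unname(tabulate(f2[y2 == 0]))), c(rep(5, 7), rep(6, 3)))
  expect_error(stratified_folds(rep(c(0L, 1L), c(9, 100)), k = 10),
               "reduce k")
})

test_that("every classifier family separates well-separated classes", {
  data <- make_gaussian_classes(30, d = 2, delta = 8, seed = 10)
  for (nm in c("svm", "knn", "naive_bayes", "decision_tree",
               "random_forest", "xgboost", "adaboost")) {
    clf <- make_classifier(classifier_spec(nm), seed = 1)
    fitted <- clf$fit(data$X, data$y)
    expect_equal(fitted$predict(data$X), data$y,
                 label = paste(nm, "training predictions"))
    s <- fitted$predict_score(data$X)
    expect_equal(auc_rank(s, data$y), 1, label = paste(nm, "training AUC"))
  }
})

test_that("classifier construction validates names and hyperparameters", {
  expect_error(classifier_spec("lgbm"), "valid names")
  expect_error(classifier_spec("svm", list(depth = 3)), "depth")
  expect_error(classifier_spec("xgboost", list(max_deep = 3)), "max_deep")
  expect_silent(classifier_spec("xgboost", list(max_depth = 3)))
})

test_that("fits are deterministic under a fixed seed", {
  data <- make_gaussian_classes(40, d = 4, delta = 1, seed = 3)
  for (nm in c("svm", "random_forest", "xgboost", "adaboost")) {
    f1 <- make_classifier(classifier_spec(nm), seed = 7)$fit(data$X, data$y)
    f2 <- make_classifier(classifier_spec(nm), seed = 7)$fit(data$X, data$y)
    expect_identical(f1$predict(data$X), f2$predict(data$X), label = nm)
    expect_identical(f1$predict_score(data$X), f2$predict_score(data$X),
                     label = nm)
  }
})

test_that("cross-validation tests each sample once and pools confusions", {
  data <- make_gaussian_classes(50, d = 3, delta = 2.5, seed = 21)
  cv <- stratified_cv(classifier_spec("naive_bayes"), data$X, data$y,
                      k = 10, seed = 5)
  expect_equal(nrow(cv$fold_table), 10)
  expect_equal(sum(cv$fold_table$n), 100)
  cm <- cv$confusion
  expect_equal(cm$tp + cm$fp + cm$fn + cm$tn, 100)
  expect_equal(cm$tp + cm$fn, sum(data$y == 1))
  expect_gte(cv$metrics$accuracy, 0.8)
  # deterministic rerun
  cv2 <- stratified_cv(classifier_spec("naive_bayes"), data$X, data$y,
                       k = 10, seed = 5)
  expect_identical(cv$metrics, cv2$metrics)
})

test_that("label-shuffled data scores near chance", {
  set.seed(55)
  X <- matrix(rnorm(120 * 4), 120, 4)
  y <- rep(c(0L, 1L), 60)[sample.int(120)]
  cv <- stratified_cv(classifier_spec("naive_bayes"), X, y, k = 10, seed = 9)
  expect_gte(cv$metrics$accuracy, 0.35)
  expect_lte(cv$metrics$accuracy, 0.65)
})
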