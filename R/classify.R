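CLASSIFIER_NAMES <- c("svm", "knn", "naive_bayes", "decision_tree",
                      "random_forest", "xgboost", "adaboost")

ALLOWED_HYPERPARAMS <- list(
  svm = c("cost", "gamma", "kernel"),
  knn = c("k"),
  naive_bayes = c("laplace"),
  decision_tree = c("maxdepth", "minsplit", "cp"),
  random_forest = c("ntree", "mtry", "nodesize"),
  xgboost = c("learning_rate", "eta", "n_estimators", "nrounds", "max_depth",
              "min_child_weight", "gamma", "subsample", "colsample_bytree"),
  adaboost = c("n_rounds", "maxdepth")
)

#' Classifier specification
#'
#' A named classifier family plus its hyperparameters, validated against the
#' family's allowed keys. Families are thin wrappers over established
#' implementations (e1071, class, rpart, randomForest, xgboost); AdaBoost is
#' a discrete AdaBoost over depth-limited rpart stumps.
#'
#' @param name One of `"svm"`, `"knn"`, `"naive_bayes"`, `"decision_tree"`,
#'   `"random_forest"`, `"xgboost"`, `"adaboost"`.
#' @param hyperparameters Named list of family-specific settings.
#' @return Object of class `classifier_spec`.
#' @export
classifier_spec <- function(name, hyperparameters = list()) {
  if (!name %in% CLASSIFIER_NAMES) {
    stop("unknown classifier '", name, "'; valid names: ",
         paste(CLASSIFIER_NAMES, collapse = ", "))
  }
  bad <- setdiff(names(hyperparameters), ALLOWED_HYPERPARAMS[[name]])
  if (length(bad) > 0) {
    stop("invalid hyperparameter(s) for ", name, ": ",
         paste(bad, collapse = ", "))
  }
  out <- list(name = name, hyperparameters = hyperparameters)
  class(out) <- "classifier_spec"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a trainable classifier from a specification
#'
#' Returns a factory exposing `fit(X, y)`; the fitted object in turn exposes
#' `predict(X)` (0/1 labels, male = positive class 1) and `predict_score(X)`
#' (a score increasing with the male class, in \[0, 1\] for probabilistic
#' families). All stochastic fits are seeded, so identical seeds give
#' identical predictions.
#'
#' @param spec A [classifier_spec()].
#' @param seed Integer seed for any stochastic component of the fit.
#' @return List with elements `spec`, `seed` and `fit`.
#' @export
make_classifier <- function(spec, seed = 1L) {
  if (!inherits(spec, "classifier_spec")) {
    spec <- classifier_spec(spec)
  }
  hp <- spec$hyperparameters
  fit <- switch(spec$name,
    svm = function(X, y) {
      set.seed(seed)
      yf <- factor(y, levels = c(0, 1))
      m <- e1071::svm(x = X, y = yf,
                      kernel = hp$kernel %||% "radial",
                      cost = hp$cost %||% 1,
                      gamma = hp$gamma %||% (1 / ncol(X)),
                      probability = TRUE)
      list(
        predict = function(Z) as.integer(as.character(stats::predict(m, Z))),
        predict_score = function(Z) {
          p <- stats::predict(m, Z, probability = TRUE)
          attr(p, "probabilities")[, "1"]
        }
      )
    },
    knn = function(X, y) {
      k <- hp$k %||% 5L
      list(
        predict = function(Z) {
          set.seed(seed)
          as.integer(as.character(
            class::knn(X, Z, factor(y, levels = c(0, 1)), k = k)))
        },
        predict_score = function(Z) {
          set.seed(seed)
          pr <- class::knn(X, Z, factor(y, levels = c(0, 1)), k = k,
                           prob = TRUE)
          win <- attr(pr, "prob")
          ifelse(pr == "1", win, 1 - win)
        }
      )
    },
    naive_bayes = function(X, y) {
      m <- e1071::naiveBayes(as.data.frame(X), factor(y, levels = c(0, 1)),
                             laplace = hp$laplace %||% 0)
      list(
        predict = function(Z) as.integer(as.character(
          stats::predict(m, as.data.frame(Z)))),
        predict_score = function(Z) stats::predict(m, as.data.frame(Z),
                                                   type = "raw")[, "1"]
      )
    },
    decision_tree = function(X, y) {
      df <- as.data.frame(X)
      df$.y <- factor(y, levels = c(0, 1))
      set.seed(seed)
      m <- rpart::rpart(.y ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          maxdepth = hp$maxdepth %||% 30,
                          minsplit = hp$minsplit %||% 20,
                          cp = hp$cp %||% 0.01))
      list(
        predict = function(Z) as.integer(as.character(
          stats::predict(m, as.data.frame(Z), type = "class"))),
        predict_score = function(Z) stats::predict(m, as.data.frame(Z),
                                                   type = "prob")[, "1"]
      )
    },
    random_forest = function(X, y) {
      set.seed(seed)
      m <- randomForest::randomForest(
        x = X, y = factor(y, levels = c(0, 1)),
        ntree = hp$ntree %||% 500,
        mtry = hp$mtry %||% max(1, floor(sqrt(ncol(X)))),
        nodesize = hp$nodesize %||% 1)
      list(
        predict = function(Z) as.integer(as.character(stats::predict(m, Z))),
        predict_score = function(Z) stats::predict(m, Z, type = "prob")[, "1"]
      )
    },
    xgboost = function(X, y) {
      params <- list(
        objective = "binary:logistic",
        eta = hp$learning_rate %||% hp$eta %||% 0.3,
        max_depth = as.integer(hp$max_depth %||% 6),
        min_child_weight = hp$min_child_weight %||% 1,
        gamma = hp$gamma %||% 0,
        subsample = hp$subsample %||% 1,
        colsample_bytree = hp$colsample_bytree %||% 1,
        nthread = 1,
        seed = seed)
      nrounds <- as.integer(hp$n_estimators %||% hp$nrounds %||% 100)
      m <- xgboost::xgb.train(params = params,
                              data = xgboost::xgb.DMatrix(as.matrix(X),
                                                          label = y),
                              nrounds = nrounds, verbose = 0)
      list(
        predict = function(Z) as.integer(
          stats::predict(m, xgboost::xgb.DMatrix(as.matrix(Z))) >= 0.5),
        predict_score = function(Z)
          stats::predict(m, xgboost::xgb.DMatrix(as.matrix(Z)))
      )
    },
    adaboost = function(X, y) {
      set.seed(seed)
      m <- adaboost_fit(X, y, n_rounds = hp$n_rounds %||% 50L,
                        maxdepth = hp$maxdepth %||% 1L)
      list(
        predict = function(Z) as.integer(adaboost_score(m, Z) >= 0.5),
        predict_score = function(Z) adaboost_score(m, Z)
      )
    }
  )
  list(spec = spec, seed = seed, fit = fit)
}

# Discrete AdaBoost with depth-limited rpart stumps. Weak-learner weights
# alpha_m = 0.5 log((1-err)/err); the score is the logistic transform of the
# weighted margin, so it is a probability-like value in (0, 1).
adaboost_fit <- function(X, y, n_rounds = 50L, maxdepth = 1L) {
  df <- as.data.frame(X)
  names(df) <- sprintf("x%04d", seq_len(ncol(df)))
  yy <- ifelse(y == 1, 1, -1)
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  dfy <- df
  dfy$.y <- factor(y, levels = c(0, 1))
  eps <- 1e-10
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = dfy, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = maxdepth,
                                                       minsplit = 2,
                                                       cp = -1, xval = 0))
    pred <- ifelse(stats::predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    err <- min(max(err, eps), 1 - eps)
    alpha <- 0.5 * log((1 - err) / err)
    if (alpha <= 0) break
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err <= eps * 2) break
  }
  list(stumps = stumps, alphas = alphas, ncol = ncol(X))
}

adaboost_score <- function(model, X) {
  df <- as.data.frame(X)
  names(df) <- sprintf("x%04d", seq_len(ncol(df)))
  f <- rep(0, nrow(df))
  for (m in seq_along(model$stumps)) {
    pred <- ifelse(stats::predict(model$stumps[[m]], df,
                                  type = "class") == "1", 1, -1)
    f <- f + model$alphas[m] * pred
  }
  1 / (1 + exp(-2 * f))
}

#' Classification metrics from a confusion matrix
#'
#' accuracy = (tp+tn)/n, precision = tp/(tp+fp), recall = tp/(tp+fn),
#' F1 = 2PR/(P+R), with the male class as positive. Ratios with zero
#' denominators are reported as 0 and flagged in `undefined`.
#'
#' @param cm Named list or vector with counts `tp`, `fp`, `fn`, `tn`.
#' @return List with `accuracy`, `precision`, `recall`, `f1` and a character
#'   vector `undefined` naming any degenerate metric.
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.list(cm)
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  if (n <= 0) stop("empty confusion matrix")
  undefined <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); 0
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); 0
  }
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    undefined <- c(undefined, "f1"); 0
  }
  list(accuracy = (tp + tn) / n, precision = precision, recall = recall,
       f1 = f1, undefined = undefined)
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney form with midranks, so tied scores contribute 1/2: perfectly
#' ranked scores give 1, reversed ranking 0, constant scores 0.5.
#'
#' @param scores Numeric scores, higher = more male-like.
#' @param labels Binary labels (0/1).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignment
#'
#' Each class is shuffled with the seeded generator and dealt round-robin
#' into k folds, so per-fold class counts differ from the exact proportion
#' by less than one.
#'
#' @param y Binary labels; each class must have at least `k` members.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment in `1..k`, one per observation.
#' @export
stratified_folds <- function(y, k = 10L, seed = 1L) {
  y <- as.integer(y)
  tab <- table(y)
  if (any(tab < k)) {
    stop("each class needs at least k = ", k,
         " members (smallest class has ", min(tab), "); reduce k")
  }
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation of a classifier
#'
#' Every sample is tested exactly once. Reported metrics are means of the
#' per-fold values; the AUC is computed from the pooled out-of-fold scores by
#' the rank statistic; the pooled confusion matrix is the sum of per-fold
#' counts.
#'
#' @param spec A [classifier_spec()] (or family name).
#' @param X Feature matrix.
#' @param y Binary labels (0 = female, 1 = male).
#' @param k Number of folds (default 10).
#' @param seed Integer seed for folds and fits.
#' @return List: `metrics` (accuracy/precision/recall/f1 fold means + pooled
#'   `auc`), `fold_table` (per-fold data frame), `confusion` (pooled tp, fp,
#'   fn, tn), `scores` and `predictions` (out-of-fold, in input order).
#' @export
stratified_cv <- function(spec, X, y, k = 10L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  folds <- stratified_folds(y, k = k, seed = seed)
  scores <- numeric(length(y))
  preds <- integer(length(y))
  fold_rows <- list()
  pooled <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (f in seq_len(k)) {
    test <- folds == f
    if (length(unique(y[!test])) < 2 || length(unique(y[test])) < 1) {
      stop("fold ", f, " lacks both classes; reduce k")
    }
    clf <- make_classifier(spec, seed = seed + f)
    fitted <- clf$fit(X[!test, , drop = FALSE], y[!test])
    p <- fitted$predict(X[test, , drop = FALSE])
    s <- fitted$predict_score(X[test, , drop = FALSE])
    preds[test] <- p
    scores[test] <- s
    cm <- c(tp = sum(p == 1 & y[test] == 1), fp = sum(p == 1 & y[test] == 0),
            fn = sum(p == 0 & y[test] == 1), tn = sum(p == 0 & y[test] == 0))
    pooled <- pooled + cm
    m <- metrics_from_confusion(as.list(cm))
    fold_rows[[f]] <- data.frame(fold = f, n = sum(test),
                                 accuracy = m$accuracy,
                                 precision = m$precision, recall = m$recall,
                                 f1 = m$f1)
  }
  fold_table <- do.call(rbind, fold_rows)
  metrics <- list(accuracy = mean(fold_table$accuracy),
                  precision = mean(fold_table$precision),
                  recall = mean(fold_table$recall),
                  f1 = mean(fold_table$f1),
                  auc = auc_rank(scores, y))
  list(metrics = metrics, fold_table = fold_table,
       confusion = as.list(pooled), scores = scores, predictions = preds)
}
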