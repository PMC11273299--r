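#' Cross-validate the full image + weight pipeline
#'
#' Stratified k-fold evaluation with every trainable stage fitted inside the
#' training fold only: the block-LDA compressor is fitted on the training
#' descriptors, training weight statistics standardize the weight feature,
#' and the classifier is trained on the fused 106-feature training matrix.
#' Test-fold specimens are transformed with the training-fold model and
#' scored out-of-fold, so the reported metrics are leakage-free.
#'
#' @param descriptors HOG descriptor matrix (n x 3780 with defaults).
#' @param weights Positive specimen weights in grams.
#' @param labels Binary sex labels (0 = female, 1 = male).
#' @param spec A [classifier_spec()] (default boosted trees).
#' @param params The [hog_params()] used for the descriptors.
#' @param k Number of stratified folds (default 10).
#' @param seed Integer seed.
#' @return As [stratified_cv()]: fold-mean metrics with pooled AUC, per-fold
#'   table, pooled confusion matrix, out-of-fold scores and predictions.
#' @export
pipeline_cv <- function(descriptors, weights, labels,
                        spec = classifier_spec("xgboost"),
                        params = hog_params(), k = 10L, seed = 1L) {
  X <- as.matrix(descriptors)
  y <- as.integer(labels)
  folds <- stratified_folds(y, k = k, seed = seed)
  scores <- numeric(length(y))
  preds <- integer(length(y))
  fold_rows <- list()
  pooled <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (f in seq_len(k)) {
    test <- folds == f
    lda <- fit_block_lda(X[!test, , drop = FALSE], y[!test], params = params)
    ws <- weight_stats(weights[!test])
    tr <- fuse_weight(transform_block_lda(lda, X[!test, , drop = FALSE]),
                      weights[!test], ws)
    te <- fuse_weight(transform_block_lda(lda, X[test, , drop = FALSE]),
                      weights[test], ws)
    clf <- make_classifier(spec, seed = seed + f)
    fitted <- clf$fit(tr, y[!test])
    p <- fitted$predict(te)
    s <- fitted$predict_score(te)
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

#' Pipeline run configuration
#'
#' @param seed Integer seed (mandatory; flows to every stochastic stage).
#' @param dataset Either a [synthetic_spec()] to generate data from, or a
#'   path to a manifest CSV of real images.
#' @param hog A [hog_params()] object.
#' @param classifier A [classifier_spec()].
#' @param folds Stratified CV folds (default 10).
#' @param mi_bins Bin count for the mutual-information estimator.
#' @param run_rfe Run recursive feature elimination (default `FALSE`; the
#'   full 106-feature path refits the classifier once per elimination step).
#' @param out_dir Optional output directory for artifacts (features CSV,
#'   metrics JSON, config echo).
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed, dataset = synthetic_spec(), hog = hog_params(),
                       classifier = classifier_spec("xgboost"), folds = 10L,
                       mi_bins = 10L, run_rfe = FALSE, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), dataset = dataset, hog = hog,
              classifier = classifier, folds = as.integer(folds),
              mi_bins = as.integer(mi_bins), run_rfe = isTRUE(run_rfe),
              out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

load_run_inputs <- function(config) {
  if (inherits(config$dataset, "synthetic_spec")) {
    ds <- generate_dataset(config$dataset)
    list(images = ds$images, weights = ds$weights, labels = ds$labels)
  } else {
    manifest <- load_manifest(config$dataset)
    base <- attr(manifest, "manifest_dir")
    paths <- ifelse(file.exists(manifest$image), manifest$image,
                    file.path(base, manifest$image))
    images <- lapply(paths, function(p) to_gray(read_specimen_image(p)))
    list(images = images, weights = manifest$weight,
         labels = manifest$label)
  }
}

#' Run the end-to-end classification pipeline
#'
#' Executes the stages in dependency order: data generation/loading,
#' preprocessing and HOG extraction, fold-wise block-LDA compression and
#' weight fusion, stratified cross-validated classification, and optionally
#' recursive feature elimination (on features fitted once on the full data,
#' for feature-importance inspection). A configuration error (e.g. folds
#' exceeding the smallest class) is raised before any heavy compute.
#'
#' @param config A [run_config()].
#' @return List with `cv` (the [pipeline_cv()] result), `n`, `class_counts`,
#'   `weight_only_accuracy`, and `rfe` when requested; artifacts are written
#'   under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  if (inherits(config$dataset, "synthetic_spec")) {
    counts <- c(config$dataset$n_female, config$dataset$n_male)
    if (any(counts < config$folds)) {
      stop("configuration error: smallest class (", min(counts),
           ") is below the fold count ", config$folds)
    }
  }
  inputs <- load_run_inputs(config)
  counts <- table(factor(inputs$labels, levels = c(0, 1)))
  if (any(counts < config$folds)) {
    stop("configuration error: smallest class (", min(counts),
         ") is below the fold count ", config$folds)
  }
  desc <- hog_matrix(inputs$images, params = config$hog)
  cv <- pipeline_cv(desc, inputs$weights, inputs$labels,
                    spec = config$classifier, params = config$hog,
                    k = config$folds, seed = config$seed)
  result <- list(cv = cv, n = length(inputs$labels),
                 class_counts = as.integer(counts),
                 weight_only_accuracy = weight_only_baseline(inputs$weights,
                                                             inputs$labels))
  if (config$run_rfe) {
    lda <- fit_block_lda(desc, inputs$labels, params = config$hog)
    fused <- fuse_weight(transform_block_lda(lda, desc), inputs$weights,
                         weight_stats(inputs$weights))
    result$rfe <- rfe(fused, inputs$labels, spec = config$classifier,
                      k = config$folds, seed = config$seed,
                      bins = config$mi_bins)
  }
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      list(metrics = cv$metrics, confusion = cv$confusion,
           n = result$n, class_counts = result$class_counts,
           weight_only_accuracy = result$weight_only_accuracy,
           seed = config$seed),
      file.path(config$out_dir, "metrics.json"),
      auto_unbox = TRUE, digits = NA)
    utils::write.csv(cv$fold_table,
                     file.path(config$out_dir, "fold_metrics.csv"),
                     row.names = FALSE)
    if (config$run_rfe) {
      utils::write.csv(result$rfe$path,
                       file.path(config$out_dir, "rfe_path.csv"),
                       row.names = FALSE)
    }
  }
  result
}
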