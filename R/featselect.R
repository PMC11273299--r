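entropy_bits <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information gain of a feature with a binary label
#'
#' IG(X; Y) = H(X) - H(X|Y) in bits. Continuous features are discretized into
#' equal-frequency (quantile) bins; the same bin edges are used for the
#' marginal and the conditional entropies, so the estimator is invariant
#' under strictly monotone transformations of the feature. With a binary
#' label the result lies in \[0, 1\] bits; tiny negative floating-point
#' residue is clipped to 0.
#'
#' @param x Numeric feature column (n >= 10).
#' @param y Binary labels (0/1), both classes present.
#' @param bins Number of equal-frequency bins (default 10).
#' @return Information gain in bits.
#' @export
mutual_info_gain <- function(x, y, bins = 10L) {
  if (length(x) < 10) stop("need at least 10 observations")
  if (length(x) != length(y)) stop("x and y lengths differ")
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  if (length(unique(x)) < 2) return(0)
  breaks <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                                   names = FALSE, type = 7))
  if (length(breaks) < 2) return(0)
  xb <- cut(x, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  n <- length(x)
  hx <- entropy_bits(tabulate(xb))
  hxy <- 0
  for (cls in c(0L, 1L)) {
    sel <- y == cls
    hxy <- hxy + sum(sel) / n * entropy_bits(tabulate(xb[sel]))
  }
  max(hx - hxy, 0)
}

#' Rank features by mutual information gain
#'
#' @param X Numeric feature matrix, n x d.
#' @param y Binary labels.
#' @param bins Equal-frequency bin count passed to [mutual_info_gain()].
#' @return Object of class `mi_ranking`: per-feature gains `ig` (bits), the
#'   rank `order` (feature indices, descending gain, ties broken by ascending
#'   index), and the bin count.
#' @export
rank_features <- function(X, y, bins = 10L) {
  X <- as.matrix(X)
  ig <- vapply(seq_len(ncol(X)), function(j) mutual_info_gain(X[, j], y, bins),
               numeric(1))
  out <- list(ig = ig, order = order(-ig, seq_along(ig)), bins = bins)
  class(out) <- "mi_ranking"
  out
}

#' Recursive feature elimination with mutual-information ranking
#'
#' Starting from the full feature set, repeatedly: evaluate the current set
#' by stratified k-fold cross-validation, re-rank the surviving features by
#' mutual information gain, and remove the single least informative feature
#' (ties broken toward the higher feature index), down to one feature. The
#' best subset is the one with maximal cross-validated accuracy, ties going
#' to the smaller subset.
#'
#' @param X Feature matrix (canonically n x 106 fused features).
#' @param y Binary labels.
#' @param spec A [classifier_spec()] evaluated at each step.
#' @param k Number of stratified CV folds.
#' @param seed Integer seed controlling fold assignment and model fits.
#' @param bins Bin count for the mutual-information estimator.
#' @return Object of class `rfe_path`: `path` data frame (iteration,
#'   n_features, removed_feature, accuracy, precision, recall, f1, auc),
#'   `active_sets` (feature indices at each step), `best` (index into the
#'   path) and `best_features`.
#' @export
rfe <- function(X, y, spec = classifier_spec("xgboost"), k = 10L, seed = 1L,
                bins = 10L) {
  X <- as.matrix(X)
  active <- seq_len(ncol(X))
  rows <- list()
  sets <- list()
  it <- 0L
  while (length(active) >= 1L) {
    it <- it + 1L
    cv <- stratified_cv(spec, X[, active, drop = FALSE], y, k = k, seed = seed)
    removed <- NA_integer_
    if (length(active) > 1L) {
      rk <- rank_features(X[, active, drop = FALSE], y, bins = bins)
      removed <- active[rk$order[length(rk$order)]]
    }
    m <- cv$metrics
    rows[[it]] <- data.frame(iteration = it, n_features = length(active),
                             removed_feature = removed,
                             accuracy = m$accuracy, precision = m$precision,
                             recall = m$recall, f1 = m$f1, auc = m$auc)
    sets[[it]] <- active
    if (length(active) == 1L) break
    active <- setdiff(active, removed)
  }
  path <- do.call(rbind, rows)
  # argmax accuracy; ties -> smaller subset (later iteration)
  best_acc <- max(path$accuracy)
  cand <- which(path$accuracy == best_acc)
  best <- cand[which.min(path$n_features[cand])]
  out <- list(path = path, active_sets = sets, best = best,
              best_features = sets[[best]])
  class(out) <- "rfe_path"
  out
}

#' @export
print.rfe_path <- function(x, ...) {
  cat("Recursive feature elimination path:", nrow(x$path), "steps\n")
  cat("Best subset:", length(x$best_features), "features, CV accuracy",
      sprintf("%.4f", x$path$accuracy[x$best]), "\n")
  invisible(x)
}
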