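#' Class means and scatter matrices
#'
#' Within-class scatter S_W = sum over classes of the centered cross-product,
#' between-class scatter S_B = sum over classes of n_c (mu_c - mu)(mu_c - mu)',
#' so that S_W + S_B equals the total scatter about the grand mean.
#'
#' @param X Numeric matrix, n x d.
#' @param y Binary labels (0/1), both classes present.
#' @return List with `mu0`, `mu1`, `mu` (grand mean), `n0`, `n1`, `Sw`, `Sb`.
#' @export
class_scatter <- function(X, y, warn_rank = TRUE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (warn_rank && nrow(X) <= ncol(X)) {
    warning("n <= d: scatter matrices are rank-deficient")
  }
  X0 <- X[y == 0L, , drop = FALSE]
  X1 <- X[y == 1L, , drop = FALSE]
  mu0 <- colMeans(X0); mu1 <- colMeans(X1); mu <- colMeans(X)
  Sw <- crossprod(sweep(X0, 2, mu0)) + crossprod(sweep(X1, 2, mu1))
  d0 <- mu0 - mu; d1 <- mu1 - mu
  Sb <- nrow(X0) * tcrossprod(d0) + nrow(X1) * tcrossprod(d1)
  list(mu0 = mu0, mu1 = mu1, mu = mu, n0 = nrow(X0), n1 = nrow(X1),
       Sw = Sw, Sb = Sb)
}

# One-dimensional Fisher discriminant direction with ridge-regularized
# within-class scatter: w ~ (S_W + lambda I)^-1 (mu1 - mu0), unit L2 norm,
# sign fixed so the male (label 1) mean projects at least as high as the
# female mean. lambda = ridge * trace(S_W) / d.
fisher_direction <- function(X, y, ridge = 1e-6, warn_rank = TRUE) {
  sc <- class_scatter(X, y, warn_rank = warn_rank)
  d <- ncol(as.matrix(X))
  dmu <- sc$mu1 - sc$mu0
  tr <- sum(diag(sc$Sw))
  if (tr == 0 && all(dmu == 0)) {
    w <- c(1, rep(0, d - 1))
    warning("degenerate all-constant block: projection set to first basis vector")
  } else if (tr == 0) {
    w <- dmu
  } else {
    lambda <- ridge * tr / d
    w <- solve(sc$Sw + diag(lambda, d), dmu)
  }
  w <- w / sqrt(sum(w^2))
  if (sum(w * sc$mu1) < sum(w * sc$mu0)) w <- -w
  w
}

# Fisher discriminant ratio (w' S_B w) / (w' S_W w) of a direction.
fisher_ratio <- function(w, Sw, Sb) {
  num <- drop(crossprod(w, Sb %*% w))
  den <- drop(crossprod(w, Sw %*% w))
  num / max(den, .Machine$double.eps)
}

#' Fit the block-wise Fisher discriminant compressor
#'
#' Partitions the HOG descriptor into its contiguous blocks (36 features per
#' block with default HOG parameters) and fits, per block, a one-dimensional
#' Fisher linear discriminant: w_b proportional to
#' (S_W + lambda I)^-1 (mu_male - mu_female) with ridge
#' lambda = 1e-6 trace(S_W)/36, normalized to unit length, sign fixed so the
#' male class projects higher. Compresses a 3780-long descriptor to one
#' coordinate per block (105 with defaults).
#'
#' @param descriptors Numeric matrix of HOG descriptors, one per row.
#' @param y Binary sex labels (0 = female, 1 = male), both present.
#' @param params The [hog_params()] the descriptors were computed with.
#' @param ridge Relative ridge on the within-class scatter.
#' @return Object of class `block_lda`: projection matrix `W`
#'   (block_len x n_blocks), offsets (per-block training means), weight of
#'   evidence metadata, and the HOG parameter fingerprint.
#' @export
fit_block_lda <- function(descriptors, y, params = hog_params(), ridge = 1e-6) {
  X <- as.matrix(descriptors)
  dims <- hog_dims(params)
  bl <- dims$block_len
  if (ncol(X) %% bl != 0) {
    stop("descriptor length ", ncol(X), " is not divisible by block width ", bl)
  }
  nb <- ncol(X) %/% bl
  if (nrow(X) <= bl) {
    warning("n <= block width (", bl, "): per-block scatter matrices are ",
            "rank-deficient; projections rely on the ridge")
  }
  W <- matrix(0, bl, nb)
  offsets <- matrix(0, bl, nb)
  for (b in seq_len(nb)) {
    cols <- ((b - 1L) * bl + 1L):(b * bl)
    Xb <- X[, cols, drop = FALSE]
    W[, b] <- fisher_direction(Xb, y, ridge = ridge, warn_rank = FALSE)
    offsets[, b] <- colMeans(Xb)
  }
  model <- list(W = W, offsets = offsets, n_blocks = nb, block_len = bl,
                n = nrow(X), n_female = sum(y == 0), n_male = sum(y == 1),
                params_hash = hog_params_hash(params), ridge = ridge)
  class(model) <- "block_lda"
  model
}

#' Project HOG descriptors through a fitted block-LDA model
#'
#' Each block coordinate is w_b' (block_b - offset_b); a 3780-long descriptor
#' becomes a 105-vector with default HOG parameters.
#'
#' @param model A fitted `block_lda` object.
#' @param descriptors Descriptor vector or matrix (one descriptor per row).
#' @return Numeric matrix n x n_blocks (a vector input gives a 1-row matrix).
#' @export
transform_block_lda <- function(model, descriptors) {
  X <- if (is.matrix(descriptors)) descriptors else matrix(descriptors, nrow = 1)
  expected <- model$n_blocks * model$block_len
  if (ncol(X) != expected) {
    stop("descriptor length mismatch: expected ", expected, ", got ", ncol(X))
  }
  out <- matrix(0, nrow(X), model$n_blocks)
  for (b in seq_len(model$n_blocks)) {
    cols <- ((b - 1L) * model$block_len + 1L):(b * model$block_len)
    w <- model$W[, b]
    out[, b] <- X[, cols, drop = FALSE] %*% w - sum(model$offsets[, b] * w)
  }
  out
}

#' @export
predict.block_lda <- function(object, newdata, ...) {
  transform_block_lda(object, newdata)
}

#' Training-split weight statistics
#'
#' @param weights Positive cocoon weights (grams) from the training split.
#' @return List with `mean` and `sd` (sample standard deviation).
#' @export
weight_stats <- function(weights) {
  if (any(weights <= 0)) stop("weights must be positive")
  s <- stats::sd(weights)
  if (!is.finite(s) || s == 0) stop("degenerate training weights: sd is zero")
  list(mean = mean(weights), sd = s)
}

#' Fuse the standardized weight feature onto block-LDA features
#'
#' Appends (weight - mean)/sd, standardized with training-split statistics
#' only, to each compressed feature vector: 105 block coordinates + 1 weight
#' = 106 features entering feature selection.
#'
#' @param features Numeric vector (one specimen) or matrix (one per row) of
#'   block-LDA coordinates.
#' @param weight Positive weight(s) in grams, one per specimen.
#' @param stats A [weight_stats()] list from the training split.
#' @return Numeric matrix with one extra trailing column, named `weight_z`.
#' @export
fuse_weight <- function(features, weight, stats) {
  X <- if (is.matrix(features)) features else matrix(features, nrow = 1)
  if (length(weight) != nrow(X)) stop("one weight per feature row required")
  if (any(weight <= 0)) stop("weights must be positive")
  if (!is.finite(stats$sd) || stats$sd <= 0) {
    stop("degenerate training weights: sd must be positive")
  }
  z <- (weight - stats$mean) / stats$sd
  out <- cbind(X, z)
  colnames(out) <- c(sprintf("f%03d", seq_len(ncol(X))), "weight_z")
  out
}
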