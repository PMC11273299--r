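#' Synthetic cocoon dataset specification
#'
#' Parameters of the seeded generator that emulates the statistical structure
#' of intact-cocoon photographs plus weights. Each specimen is a bright
#' ellipse (the cocoon) on a dark background. The sex signal is carried by
#' subtle shape and surface-texture differences — ellipse axis ratio and the
#' spatial frequency of a multiplicative sinusoidal texture — at matched
#' ellipse area, so single-pixel statistics (e.g. mean intensity) are weak
#' classifiers. Per-class weight distributions overlap strongly (default
#' Cohen's d = 0.3), encoding the premise that weight alone cannot classify
#' the sexes when the pupa is inside the cocoon.
#'
#' @param n_male,n_female Specimen counts per class.
#' @param img_height,img_width Pre-resize image geometry (default 160 x 90).
#' @param axis_ratio_male,axis_ratio_female Mean ellipse major/minor axis
#'   ratios (defaults 2.30 / 2.10).
#' @param axis_ratio_sd Within-class axis-ratio standard deviation (0.08).
#' @param texture_freq_male,texture_freq_female Sinusoidal surface-texture
#'   frequency in cycles per pixel along the major axis.
#' @param texture_amp Texture amplitude (multiplicative, relative).
#' @param noise_sd Additive Gaussian pixel noise sd on the 0-255 scale.
#' @param weight_mean_male,weight_mean_female Class weight means in grams
#'   (defaults 1.10 / 1.16).
#' @param weight_sd Common weight sd in grams (default 0.20, giving d = 0.3).
#' @param seed Integer seed; the dataset is a pure function of this spec.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_male = 800L, n_female = 800L,
                           img_height = 160L, img_width = 90L,
                           axis_ratio_male = 2.30, axis_ratio_female = 2.10,
                           axis_ratio_sd = 0.08,
                           texture_freq_male = 0.14,
                           texture_freq_female = 0.10,
                           texture_amp = 0.18, noise_sd = 10,
                           weight_mean_male = 1.10,
                           weight_mean_female = 1.16, weight_sd = 0.20,
                           seed = 1L) {
  if (n_male <= 0 || n_female <= 0) stop("class counts must be positive")
  if (axis_ratio_sd <= 0 || weight_sd <= 0 || noise_sd < 0) {
    stop("standard deviations must be positive")
  }
  sp <- list(n_male = as.integer(n_male), n_female = as.integer(n_female),
             img_height = as.integer(img_height),
             img_width = as.integer(img_width),
             axis_ratio_male = axis_ratio_male,
             axis_ratio_female = axis_ratio_female,
             axis_ratio_sd = axis_ratio_sd,
             texture_freq_male = texture_freq_male,
             texture_freq_female = texture_freq_female,
             texture_amp = texture_amp, noise_sd = noise_sd,
             weight_mean_male = weight_mean_male,
             weight_mean_female = weight_mean_female,
             weight_sd = weight_sd, seed = as.integer(seed))
  class(sp) <- "synthetic_spec"
  sp
}

#' FC1-composition preset
#'
#' Synthetic dataset matching the composition of the FC1 foundation-cross
#' variety sample: 1579 specimens, 837 male and 742 female.
#'
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
synthetic_spec_fc1 <- function(seed = 1L, ...) {
  synthetic_spec(n_male = 837L, n_female = 742L, seed = seed, ...)
}

#' FC2-composition preset
#'
#' Synthetic dataset matching the composition of the FC2 foundation-cross
#' variety sample: 1669 specimens, 832 male and 837 female.
#'
#' @inheritParams synthetic_spec_fc1
#' @return A `synthetic_spec`.
#' @export
synthetic_spec_fc2 <- function(seed = 1L, ...) {
  synthetic_spec(n_male = 832L, n_female = 837L, seed = seed, ...)
}

#' Render one synthetic cocoon image
#'
#' Draws a bright, dome-shaded filled ellipse with class-dependent axis ratio
#' (jittered rotation, area held fixed across classes) on a dark background,
#' multiplies the foreground by a class-dependent sinusoidal surface texture
#' with random phase, and adds Gaussian pixel noise. Consumes draws from the
#' current R random stream, so it is deterministic under the caller's seed.
#'
#' @param label Class label (0 = female, 1 = male).
#' @param spec A [synthetic_spec()].
#' @return Intensity matrix `img_height` x `img_width` in \[0, 255\].
#' @export
generate_cocoon_image <- function(label, spec) {
  h <- spec$img_height; w <- spec$img_width
  ratio_mu <- if (label == 1) spec$axis_ratio_male else spec$axis_ratio_female
  freq0 <- if (label == 1) spec$texture_freq_male else spec$texture_freq_female
  ratio <- max(stats::rnorm(1, ratio_mu, spec$axis_ratio_sd), 1.2)
  # fixed ellipse area: a/b = ratio, pi*a*b = pi*a0*b0
  a0 <- 0.38 * h; b0 <- 0.30 * w
  b <- sqrt(a0 * b0 / ratio)
  a <- ratio * b
  theta <- stats::rnorm(1, 0, 5) * pi / 180
  cy <- h / 2 + stats::rnorm(1, 0, 1.5)
  cx <- w / 2 + stats::rnorm(1, 0, 1.5)
  phase <- stats::runif(1, 0, 2 * pi)
  freq <- freq0 * stats::rnorm(1, 1, 0.05)
  rows <- matrix(seq_len(h), h, w) - cy
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- rows * cos(theta) + cols * sin(theta)   # along major (vertical) axis
  v <- -rows * sin(theta) + cols * cos(theta)
  r2 <- (u / a)^2 + (v / b)^2
  inside <- r2 <= 1
  shade <- sqrt(pmax(1 - r2, 0))               # dome shading
  texture <- 1 + spec$texture_amp * sin(2 * pi * freq * u + phase)
  img <- 30 + inside * (60 + 140 * shade) * texture
  img <- img + stats::rnorm(h * w, 0, spec$noise_sd)
  matrix(pmin(pmax(img, 0), 255), h, w)
}

#' Generate a seeded synthetic cocoon dataset
#'
#' Produces `n_male + n_female` specimens in a seeded shuffled order, each
#' with an image, a per-class Gaussian weight (truncated at zero) and a sex
#' label. All randomness flows from `spec$seed`: the dataset is a pure
#' function of the specification.
#'
#' @param spec A [synthetic_spec()].
#' @return Object of class `synthetic_dataset`: `images` (list of intensity
#'   matrices), `weights`, `labels`, `spec`, `seed`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  labels <- c(rep(1L, spec$n_male), rep(0L, spec$n_female))
  labels <- labels[sample.int(length(labels))]
  n <- length(labels)
  weights <- numeric(n)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    mu <- if (labels[i] == 1) spec$weight_mean_male else spec$weight_mean_female
    wgt <- stats::rnorm(1, mu, spec$weight_sd)
    while (wgt <= 0) wgt <- stats::rnorm(1, mu, spec$weight_sd)
    weights[i] <- wgt
    images[[i]] <- generate_cocoon_image(labels[i], spec)
  }
  out <- list(images = images, weights = weights, labels = labels,
              spec = spec, seed = spec$seed)
  class(out) <- "synthetic_dataset"
  out
}

#' Best single-threshold accuracy of weight alone
#'
#' Brute-forces every threshold (midpoints between sorted distinct weights)
#' in both polarities and returns the best training accuracy a
#' weight-threshold classifier can reach. Used to verify that weight alone
#' is a weak classifier under the default overlap.
#'
#' @param weights Numeric weights, or a `synthetic_dataset`.
#' @param labels Binary labels (ignored when `weights` is a dataset).
#' @return Best achievable single-threshold accuracy.
#' @export
weight_only_baseline <- function(weights, labels = NULL) {
  if (inherits(weights, "synthetic_dataset")) {
    labels <- weights$labels
    weights <- weights$weights
  }
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  sw <- sort(unique(weights))
  thr <- c(sw[1] - 1, (sw[-1] + sw[-length(sw)]) / 2, sw[length(sw)] + 1)
  n <- length(weights)
  best <- 0
  for (t in thr) {
    acc <- mean((weights > t) == (labels == 1))
    best <- max(best, acc, 1 - acc)
  }
  best
}

#' Write a synthetic dataset as images plus manifest
#'
#' Writes one PNG per specimen and a `manifest.csv` with the schema expected
#' by [load_manifest()] (`image`, `weight`, `label`, `variety`).
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @param variety Variety tag recorded in the manifest (default "SYN").
#' @return Path to the manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir, variety = "SYN") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$images)
  files <- sprintf("cocoon_%05d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(dataset$images[[i]] / 255, file.path(dir, files[i]))
  }
  manifest <- data.frame(image = files, weight = dataset$weights,
                         label = dataset$labels, variety = variety)
  path <- file.path(dir, "manifest.csv")
  write_manifest(manifest, path)
  invisible(path)
}
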