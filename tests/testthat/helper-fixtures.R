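# Fixture builders and independent oracles shared across test files.

# Direct sliding-window linear convolution: brute-force oracle for the FFT
# path. Returns the full (zero-padded) convolution.
direct_convolve_full <- function(g, f) {
  nr <- nrow(g); nc <- ncol(g); kr <- nrow(f); kc <- ncol(f)
  out <- matrix(0, nr + kr - 1, nc + kc - 1)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i:(i + kr - 1), j:(j + kc - 1)] <-
        out[i:(i + kr - 1), j:(j + kc - 1)] + g[i, j] * f
    }
  }
  out
}

# Shannon entropy in bits of a count vector.
entropy2 <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Small labeled Gaussian 2-class dataset, well separated when delta is large.
make_gaussian_classes <- function(n_per_class, d = 2, delta = 3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d), n_per_class, d),
             matrix(rnorm(n_per_class * d, mean = 0), n_per_class, d))
  X[(n_per_class + 1):(2 * n_per_class), 1] <-
    X[(n_per_class + 1):(2 * n_per_class), 1] + delta
  list(X = X, y = rep(c(0L, 1L), each = n_per_class))
}

# Random 128 x 64 test image.
random_image <- function(seed, h = 128, w = 64) {
  set.seed(seed)
  matrix(runif(h * w, 0, 255), h, w)
}

# Sphere benchmark fitness on normalized genes: maximal (1) at 0.5 per gene.
sphere_fitness <- function(genes) 1 - mean((genes - 0.5)^2) * 4
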