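test_that("gradients match hand-computed central differences on ramps", {
  const <- matrix(5, 16, 16)
  g <- compute_gradients(const)
  expect_true(all(g$magnitude == 0))
  expect_true(all(g$orientation == 0))

  col_ramp <- matrix(rep(1:16, each = 16), 16, 16)
  g <- compute_gradients(col_ramp)
  expect_equal(g$gx[5, 5], 2)
  expect_equal(g$gy[5, 5], 0)
  expect_equal(g$magnitude[5, 5], 2)
  expect_equal(g$orientation[5, 5], 0)

  row_ramp <- matrix(rep(1:16, times = 16), 16, 16)
  g <- compute_gradients(row_ramp)
  expect_equal(g$magnitude[5, 5], 2)
  expect_equal(g$orientation[5, 5], 90)

  # magnitude identity holds everywhere
  img <- random_image(7, 32, 32)
  g <- compute_gradients(img)
  expect_equal(g$magnitude, sqrt(g$gx^2 + g$gy^2))
  expect_true(all(g$orientation >= 0 & g$orientation < 180))
})

test_that("filter bank is num_bins all-ones summation kernels", {
  bank <- build_filter_bank(hog_params())
  expect_length(bank$filters, 9)
  expect_true(all(vapply(bank$filters,
                         function(f) all(f == 1) && all(dim(f) == c(8, 8)),
                         logical(1))))
  expect_equal(sum(bank$filters[[1]]), 64)
  expect_length(build_filter_bank(hog_params(num_bins = 2))$filters, 2)
})

test_that("FFT convolution equals brute-force spatial convolution", {
  set.seed(31)
  g <- matrix(rnorm(32 * 32), 32, 32)
  f <- matrix(1, 8, 8)
  full <- fft_convolve(g, f, shape = "full")
  oracle <- direct_convolve_full(g, f)
  expect_lt(max(abs(full - oracle)) / max(abs(oracle)), 1e-9)

  # asymmetric kernel too
  f2 <- matrix(rnorm(15), 3, 5)
  expect_lt(max(abs(fft_convolve(g, f2, shape = "full") -
                    direct_convolve_full(g, f2))), 1e-9)

  # identity kernel and zero image
  expect_equal(fft_convolve(g, matrix(1, 1, 1)), g)
  expect_equal(fft_convolve(matrix(0, 10, 10), f),
               matrix(0, 10, 10))

  expect_error(fft_convolve(matrix(1, 4, 4), matrix(1, 5, 5)), "larger")
})

test_that("FFT cell histograms equal direct per-cell accumulation", {
  p <- hog_params()
  zero <- compute_gradients(matrix(1, 128, 64))
  expect_true(all(fft_cell_histograms(zero, p) == 0))

  # column ramp: all mass in the 0-degree bin, per cell = sum of magnitudes
  ramp <- matrix(rep(seq_len(64) * 3, each = 128), 128, 64)
  g <- compute_gradients(ramp)
  h <- fft_cell_histograms(g, p)
  expect_true(all(h[, , 2:9] == 0))
  expect_equal(h[3, 3, 1], sum(g$magnitude[17:24, 17:24]))

  img <- random_image(12)
  g <- compute_gradients(img)
  expect_lt(max(abs(fft_cell_histograms(g, p) -
                    pupasex:::direct_cell_histograms(g, p))), 1e-9)
})

test_that("descriptor layout arithmetic holds across parameter settings", {
  cases <- list(
    list(p = hog_params(), len = 3780),
    list(p = hog_params(cell_size = 16), len = ((128 / 16 - 2) + 1) *
           ((64 / 16 - 2) + 1) * 4 * 9),
    list(p = hog_params(num_bins = 6), len = 105 * 4 * 6),
    list(p = hog_params(block_size = 2, block_stride = 2),
         len = 8 * 4 * 36)
  )
  for (cs in cases) {
    expect_equal(hog_dims(cs$p)$length, cs$len)
    img <- random_image(5)
    expect_length(hog_features(img, cs$p), cs$len)
  }
  expect_error(hog_params(cell_size = 7), "divide")
})

test_that("block normalization bounds norms and guards the zero block", {
  p <- hog_params()
  zero <- array(0, c(16, 8, 9))
  d <- normalize_and_flatten(zero, p)
  expect_true(all(d == 0))
  expect_false(any(is.nan(d)))

  img <- random_image(3)
  d <- hog_features(img, p)
  blocks <- matrix(d, nrow = 36)
  norms <- sqrt(colSums(blocks^2))
  expect_true(all(norms <= 1 + 1e-9))
  expect_true(all(norms[colSums(abs(blocks)) > 0] > 0))
})

test_that("accelerated and reference HOG agree; descriptor ignores DC", {
  for (s in 1:5) {
    img <- random_image(s)
    expect_lt(max(abs(hog_features(img) - hog_reference(img))), 1e-6)
  }
  img <- random_image(99)
  expect_equal(hog_features(img), hog_features(img + 40))
  # repeated calls bit-identical
  expect_identical(hog_reference(img), hog_reference(img))
})

test_that("hog_matrix resizes and stacks one descriptor per image", {
  imgs <- list(matrix(runif(100 * 50), 100, 50), random_image(2))
  M <- hog_matrix(imgs)
  expect_equal(dim(M), c(2L, 3780L))
})
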