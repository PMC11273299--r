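#' HOG descriptor parameters
#'
#' Parameter record for the histogram-of-oriented-gradients descriptor.
#' The defaults (8-pixel cells, 2x2-cell blocks at 1-cell stride, 9 unsigned
#' orientation bins, L2 block normalization) on a 128 x 64 window give the
#' classical 105-block, 3780-long descriptor.
#'
#' @param cell_size Cell side length in pixels; must divide both 128 and 64.
#' @param block_size Block side length in cells.
#' @param block_stride Block stride in cells.
#' @param num_bins Number of orientation histogram bins (>= 2).
#' @param signed If `FALSE` (default) orientations are folded to \[0, 180).
#' @param norm Block normalization scheme; only `"L2"` is supported.
#' @return An object of class `hog_params`.
#' @export
hog_params <- function(cell_size = 8L, block_size = 2L, block_stride = 1L,
                       num_bins = 9L, signed = FALSE, norm = "L2") {
  cell_size <- as.integer(cell_size)
  if (128L %% cell_size != 0L || 64L %% cell_size != 0L) {
    stop("cell_size must divide both 128 and 64")
  }
  if (num_bins < 2) stop("num_bins must be >= 2")
  if (!identical(norm, "L2")) stop("only L2 block normalization is supported")
  p <- list(cell_size = cell_size, block_size = as.integer(block_size),
            block_stride = as.integer(block_stride),
            num_bins = as.integer(num_bins), signed = isTRUE(signed),
            norm = norm)
  class(p) <- "hog_params"
  p
}

# Deterministic fingerprint used to check descriptor/model layout
# compatibility across fits and transforms.
hog_params_hash <- function(params) {
  paste(params$cell_size, params$block_size, params$block_stride,
        params$num_bins, as.integer(params$signed), params$norm, sep = ":")
}

#' Descriptor geometry implied by a parameter set
#'
#' @param params A [hog_params()] object.
#' @param height,width Window geometry (default 128 x 64).
#' @return List with cell-grid and block-grid shapes, `n_blocks`,
#'   `block_len` (features per block) and total `length`.
#' @export
hog_dims <- function(params, height = 128L, width = 64L) {
  ncr <- height %/% params$cell_size
  ncc <- width %/% params$cell_size
  nbr <- (ncr - params$block_size) %/% params$block_stride + 1L
  nbc <- (ncc - params$block_size) %/% params$block_stride + 1L
  block_len <- params$block_size^2 * params$num_bins
  list(cells = c(ncr, ncc), blocks = c(nbr, nbc),
       n_blocks = nbr * nbc, block_len = block_len,
       length = nbr * nbc * block_len)
}

#' Image gradients for HOG
#'
#' Central differences with the \[-1, 0, 1\] kernel along columns (x) and rows
#' (y), replicate padding at the borders. Orientation is the arctangent of
#' gy/gx in degrees, folded to \[0, 180) for unsigned gradients; pixels with
#' zero magnitude get orientation 0 by convention.
#'
#' @param img Numeric intensity matrix.
#' @param signed Keep the full \[0, 360) orientation range if `TRUE`.
#' @return Object of class `gradient_field` with elements `gx`, `gy`,
#'   `magnitude`, `orientation`.
#' @export
compute_gradients <- function(img, signed = FALSE) {
  if (any(!is.finite(img))) stop("image contains non-finite values")
  h <- nrow(img); w <- ncol(img)
  gx <- img[, c(2:w, w), drop = FALSE] - img[, c(1, 1:(w - 1)), drop = FALSE]
  gy <- img[c(2:h, h), , drop = FALSE] - img[c(1, 1:(h - 1)), , drop = FALSE]
  mag <- sqrt(gx^2 + gy^2)
  ori <- atan2(gy, gx) * 180 / pi
  ori <- if (signed) ori %% 360 else ori %% 180
  ori[mag == 0] <- 0
  out <- list(gx = gx, gy = gy, magnitude = mag, orientation = ori)
  class(out) <- "gradient_field"
  out
}

#' Orientation filter bank for frequency-domain cell aggregation
#'
#' One spatial filter per orientation bin. Each filter is the
#' cell_size x cell_size all-ones summation kernel; paired with the hard
#' per-bin orientation masks, convolving the bin-masked magnitude image with
#' its filter yields every cell's bin histogram entry at the cell anchors.
#'
#' @param params A [hog_params()] object.
#' @return Object of class `orientation_filter_bank`: list of `num_bins`
#'   kernels plus the bin break points in degrees.
#' @export
build_filter_bank <- function(params) {
  span <- if (params$signed) 360 else 180
  filters <- replicate(params$num_bins,
                       matrix(1, params$cell_size, params$cell_size),
                       simplify = FALSE)
  bank <- list(filters = filters,
               breaks = seq(0, span, length.out = params$num_bins + 1L),
               params = params)
  class(bank) <- "orientation_filter_bank"
  bank
}

#' Linear convolution via the FFT
#'
#' Zero-padded (linear, not circular) convolution computed in the frequency
#' domain: forward transforms, pointwise product, inverse transform. The
#' imaginary residue of the inverse transform is checked to be negligible
#' before being discarded.
#'
#' @param g Numeric matrix (image).
#' @param f Numeric matrix (kernel), no larger than `g` in either dimension.
#' @param shape `"same"` (default) crops to the geometry of `g`, centered on
#'   the kernel anchor; `"full"` returns the complete linear convolution.
#' @return Numeric matrix of the convolution.
#' @export
fft_convolve <- function(g, f, shape = c("same", "full")) {
  shape <- match.arg(shape)
  nr <- nrow(g); nc <- ncol(g); kr <- nrow(f); kc <- ncol(f)
  if (kr > nr || kc > nc) {
    stop("kernel (", kr, "x", kc, ") larger than image (", nr, "x", nc, ")")
  }
  fr <- nr + kr - 1L; fc <- nc + kc - 1L
  P <- stats::nextn(fr, c(2, 3, 5))
  Q <- stats::nextn(fc, c(2, 3, 5))
  G <- matrix(0, P, Q); G[1:nr, 1:nc] <- g
  FK <- matrix(0, P, Q); FK[1:kr, 1:kc] <- f
  C <- stats::fft(stats::fft(G) * stats::fft(FK), inverse = TRUE) / (P * Q)
  C <- C[1:fr, 1:fc, drop = FALSE]
  scale <- max(1, max(abs(Re(C))))
  if (max(abs(Im(C))) > 1e-6 * scale) {
    stop("imaginary residue of inverse FFT exceeds tolerance")
  }
  C <- Re(C)
  if (shape == "full") return(C)
  r0 <- (kr - 1L) %/% 2L
  c0 <- (kc - 1L) %/% 2L
  C[(r0 + 1L):(r0 + nr), (c0 + 1L):(c0 + nc), drop = FALSE]
}

# Hard orientation-bin index per pixel (no bilinear vote between bins).
orientation_bins <- function(orientation, params) {
  span <- if (params$signed) 360 else 180
  binw <- span / params$num_bins
  pmin(floor(orientation / binw) + 1L, params$num_bins)
}

#' Cell histograms by frequency-domain convolution
#'
#' For every orientation bin the magnitude image is masked to pixels falling
#' in that bin and convolved (via [fft_convolve()]) with the bin's all-ones
#' summation kernel; sampling the full convolution at the cell anchor points
#' gives each cell's histogram entry for that bin.
#'
#' @param grad A `gradient_field` from [compute_gradients()].
#' @param params A [hog_params()] object.
#' @return Array of cell histograms, `n_cell_rows x n_cell_cols x num_bins`.
#' @export
fft_cell_histograms <- function(grad, params = hog_params()) {
  mag <- grad$magnitude
  h <- nrow(mag); w <- ncol(mag); cs <- params$cell_size
  if (h %% cs != 0 || w %% cs != 0) stop("image dims must be multiples of cell_size")
  ncr <- h %/% cs; ncc <- w %/% cs
  bins <- orientation_bins(grad$orientation, params)
  bank <- build_filter_bank(params)
  out <- array(0, c(ncr, ncc, params$num_bins))
  anchor_r <- cs * seq_len(ncr)
  anchor_c <- cs * seq_len(ncc)
  for (k in seq_len(params$num_bins)) {
    masked <- mag * (bins == k)
    full <- fft_convolve(masked, bank$filters[[k]], shape = "full")
    out[, , k] <- full[anchor_r, anchor_c]
  }
  out
}

# Direct spatial-domain cell accumulation: the numerical oracle for the
# FFT path.
direct_cell_histograms <- function(grad, params = hog_params()) {
  mag <- grad$magnitude
  h <- nrow(mag); w <- ncol(mag); cs <- params$cell_size
  ncr <- h %/% cs; ncc <- w %/% cs
  bins <- orientation_bins(grad$orientation, params)
  out <- array(0, c(ncr, ncc, params$num_bins))
  for (i in seq_len(ncr)) {
    rs <- ((i - 1L) * cs + 1L):(i * cs)
    for (j in seq_len(ncc)) {
      csel <- ((j - 1L) * cs + 1L):(j * cs)
      m <- mag[rs, csel]
      b <- bins[rs, csel]
      for (k in seq_len(params$num_bins)) {
        out[i, j, k] <- sum(m[b == k])
      }
    }
  }
  out
}

#' Block-normalize cell histograms and flatten to the HOG descriptor
#'
#' Slides a block_size x block_size cell window at block_stride, L2-normalizes
#' each block vector as v / sqrt(||v||^2 + eps^2) with eps = 1e-10 (all-zero
#' blocks map to zero, never NaN), and concatenates blocks in row-major scan
#' order; within a block cells are row-major, within a cell the bins are in
#' ascending orientation order.
#'
#' @param cells Cell-histogram array from [fft_cell_histograms()].
#' @param params A [hog_params()] object.
#' @return Numeric HOG descriptor vector.
#' @export
normalize_and_flatten <- function(cells, params = hog_params()) {
  d <- dim(cells)
  ncr <- d[1]; ncc <- d[2]; nb <- params$block_size; st <- params$block_stride
  eps2 <- 1e-20
  br_starts <- seq(1L, ncr - nb + 1L, by = st)
  bc_starts <- seq(1L, ncc - nb + 1L, by = st)
  block_len <- nb * nb * params$num_bins
  out <- numeric(length(br_starts) * length(bc_starts) * block_len)
  pos <- 0L
  for (br in br_starts) {
    for (bc in bc_starts) {
      v <- numeric(block_len)
      q <- 0L
      for (cr in br:(br + nb - 1L)) {
        for (cc in bc:(bc + nb - 1L)) {
          v[(q + 1L):(q + params$num_bins)] <- cells[cr, cc, ]
          q <- q + params$num_bins
        }
      }
      v <- v / sqrt(sum(v^2) + eps2)
      out[(pos + 1L):(pos + block_len)] <- v
      pos <- pos + block_len
    }
  }
  out
}

#' HOG descriptor of a 128 x 64 grayscale image
#'
#' The production path aggregates cell histograms by frequency-domain
#' convolution (`method = "fft"`); `method = "reference"` uses direct
#' spatial-domain accumulation and serves as the numerical oracle. Both
#' paths share gradients and block normalization and agree to within
#' floating-point round-off.
#'
#' @param img Numeric intensity matrix whose dimensions are multiples of
#'   `cell_size` (canonically 128 x 64; see [resize_canonical()]).
#' @param params A [hog_params()] object.
#' @param method `"fft"` or `"reference"`.
#' @return Numeric descriptor vector (length 3780 with defaults).
#' @export
hog_features <- function(img, params = hog_params(),
                         method = c("fft", "reference")) {
  method <- match.arg(method)
  grad <- compute_gradients(img, signed = params$signed)
  cells <- if (method == "fft") {
    fft_cell_histograms(grad, params)
  } else {
    direct_cell_histograms(grad, params)
  }
  normalize_and_flatten(cells, params)
}

#' Reference (spatial-domain) HOG descriptor
#'
#' Equivalent contract to [hog_features()] with `method = "fft"` but computed
#' by direct per-cell accumulation; used as the equivalence oracle for the
#' accelerated path.
#'
#' @inheritParams hog_features
#' @return Numeric descriptor vector.
#' @export
hog_reference <- function(img, params = hog_params()) {
  hog_features(img, params, method = "reference")
}

#' Extract HOG descriptors for a list of images
#'
#' @param images List of intensity matrices (resized to the canonical
#'   geometry beforehand, or resizable: any matrix is passed through
#'   [resize_canonical()] when `resize = TRUE`).
#' @param params A [hog_params()] object.
#' @param method Passed to [hog_features()].
#' @param resize Resize each image to 128 x 64 first (default `TRUE`).
#' @return Numeric matrix, one descriptor per row.
#' @export
hog_matrix <- function(images, params = hog_params(), method = "fft",
                       resize = TRUE) {
  n <- length(images)
  len <- hog_dims(params)$length
  out <- matrix(0, n, len)
  for (i in seq_len(n)) {
    img <- images[[i]]
    if (resize) img <- resize_canonical(img)
    out[i, ] <- hog_features(img, params, method = method)
  }
  out
}
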