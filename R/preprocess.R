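#' Load a specimen manifest
#'
#' Reads a CSV manifest describing one specimen per row. Required columns are
#' `image` (path to the cocoon photograph, relative paths resolved against the
#' manifest's directory), `weight` (cocoon-plus-pupa weight in grams, must be
#' positive) and `label` (0 = female, 1 = male). An optional `variety` column
#' (e.g. "FC1"/"FC2") is carried through untouched.
#'
#' @param path Path to the manifest CSV.
#' @return A data frame with columns `image`, `weight`, `label` and, when
#'   present, `variety`, one row per specimen in file order.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image", "weight", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("manifest is missing required column(s): ", paste(missing, collapse = ", "))
  }
  df$weight <- as.numeric(df$weight)
  df$label <- as.integer(df$label)
  bad_w <- which(!is.finite(df$weight) | df$weight <= 0)
  if (length(bad_w) > 0) {
    stop("non-positive or missing weight in manifest row ", bad_w[1])
  }
  bad_l <- which(!(df$label %in% c(0L, 1L)))
  if (length(bad_l) > 0) {
    stop("label must be 0 (female) or 1 (male); offending manifest row ", bad_l[1])
  }
  keep <- c(required, intersect("variety", names(df)))
  df <- df[, keep, drop = FALSE]
  attr(df, "manifest_dir") <- dirname(normalizePath(path, mustWork = FALSE))
  df
}

#' Write a specimen manifest
#'
#' Inverse of [load_manifest()]; round-tripping preserves the
#' specimen/weight/label association exactly.
#'
#' @param manifest Data frame with columns `image`, `weight`, `label` and
#'   optionally `variety`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a color image to grayscale
#'
#' Applies the ITU-R BT.601 luma combination 0.299 R + 0.587 G + 0.114 B.
#' A matrix (already-gray) input passes through unchanged, so the operation is
#' idempotent.
#'
#' @param img Either an H x W numeric matrix or an H x W x 3 array with
#'   channel values in \[0, 255\].
#' @return An H x W numeric matrix of intensities.
#' @export
to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  d <- dim(img)
  if (length(d) == 3 && d[3] == 1) return(img[, , 1])
  if (length(d) == 3 && d[3] == 3) {
    return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
  }
  stop("unsupported image format: expected 1 or 3 channels, got ",
       if (length(d) == 3) d[3] else paste(d, collapse = "x"))
}

# Bilinear resampling with the align-centers convention: output pixel centers
# are mapped uniformly onto input pixel centers, so a constant image stays
# constant and values never leave [min(img), max(img)].
resize_bilinear <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (h == out_h && w == out_w) return(img)
  rs <- (seq_len(out_h) - 0.5) * h / out_h + 0.5
  cs <- (seq_len(out_w) - 0.5) * w / out_w + 0.5
  r0 <- pmin(pmax(floor(rs), 1), h)
  c0 <- pmin(pmax(floor(cs), 1), w)
  r1 <- pmin(r0 + 1, h)
  c1 <- pmin(c0 + 1, w)
  fr <- pmin(pmax(rs - r0, 0), 1)
  fc <- pmin(pmax(cs - c0, 0), 1)
  FR <- matrix(fr, out_h, out_w)
  FC <- matrix(fc, out_h, out_w, byrow = TRUE)
  top <- img[r0, c0, drop = FALSE] * (1 - FC) + img[r0, c1, drop = FALSE] * FC
  bot <- img[r1, c0, drop = FALSE] * (1 - FC) + img[r1, c1, drop = FALSE] * FC
  top * (1 - FR) + FR * bot
}

#' Resize an intensity image to the canonical HOG geometry
#'
#' Bilinear resize to 128 rows x 64 columns (height x width), the standard
#' HOG detection-window shape. Aspect ratio is not preserved: the image is
#' stretched directly onto the target grid.
#'
#' @param img Nonempty numeric matrix of intensities.
#' @param height,width Target geometry; defaults 128 x 64.
#' @return A `height` x `width` numeric matrix.
#' @export
resize_canonical <- function(img, height = 128L, width = 64L) {
  if (!is.matrix(img) || nrow(img) < 1 || ncol(img) < 1) {
    stop("resize_canonical() requires a nonempty 2-D intensity grid")
  }
  if (any(!is.finite(img))) stop("image contains non-finite values")
  resize_bilinear(img, height, width)
}

#' Read a specimen image from disk
#'
#' Supports PNG, TIFF and JPEG. Pixel values are rescaled to \[0, 255\].
#'
#' @param path Image file path.
#' @return A numeric matrix (gray input) or H x W x 3 array (color input).
#' @export
read_specimen_image <- function(path) {
  if (!file.exists(path)) stop("image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '.", ext, "': expected png, tiff or jpeg")
  )
  img * 255
}

#' Load and preprocess one specimen image
#'
#' Convenience composition: read from disk, grayscale, resize to the
#' canonical 128 x 64 HOG window.
#'
#' @inheritParams read_specimen_image
#' @return A 128 x 64 numeric intensity matrix.
#' @export
preprocess_image <- function(path) {
  resize_canonical(to_gray(read_specimen_image(path)))
}
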