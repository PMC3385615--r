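#' Image and mask containers
#'
#' A `raw_image` is a 2-D integer intensity grid as acquired (12-bit range,
#' 0--4095, for scanner data). A `roi_mask` is a binary matrix of the same
#' dimensions marking the liver region of interest. Both use row-major,
#' origin top-left, 1-based matrix indexing throughout the package.
#'
#' @param pixels Integer matrix of non-negative intensities.
#' @param subject_id Character scalar identifying the subject.
#' @param bit_depth Integer; pixel values must lie in `[0, 2^bit_depth - 1]`.
#' @return `raw_image()` returns an object of class `raw_image` with elements
#'   `pixels`, `subject_id`, `bit_depth`, `height`, `width`.
#' @export
raw_image <- function(pixels, subject_id = "subject", bit_depth = 12L) {
  if (!is.matrix(pixels)) abort("`pixels` must be a matrix")
  px <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  if (anyNA(px) || any(px < 0L)) abort("pixel values must be non-negative integers")
  if (any(px > 2^bit_depth - 1)) {
    abort(sprintf("pixel values exceed the %d-bit range [0, %d]", bit_depth, 2^bit_depth - 1))
  }
  structure(
    list(pixels = px, subject_id = as.character(subject_id),
         bit_depth = as.integer(bit_depth),
         height = nrow(px), width = ncol(px)),
    class = "raw_image"
  )
}

#' @export
print.raw_image <- function(x, ...) {
  cat(sprintf("<raw_image> %s: %d x %d, %d-bit, range [%d, %d]\n",
              x$subject_id, x$height, x$width, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a single-slice MR image
#'
#' Reads a 2-D grayscale image from DICOM (single-frame, little-endian),
#' 16-bit (or 8-bit) grayscale PNG, or TIFF. For DICOM, the bit depth is
#' taken from BitsStored and the rescale slope/intercept are applied only
#' when both are present and yield integer values (the pipeline operates on
#' the scanner's stored-value range). For PNG/TIFF the file's declared bit
#' depth is used, falling back to 16.
#'
#' @param path Path to the image file.
#' @param subject_id Optional subject id; defaults to the file name stem.
#' @return A [raw_image()].
#' @export
read_image <- function(path, subject_id = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read image, file not found: ", path))
  sid <- subject_id %||% tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("dcm", "dicom", "ima") || is_dicom_file(path)) {
    return(read_dicom_image(path, subject_id = sid))
  }
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (length(dim(img)) == 3L) {
      abort(paste0("unsupported format (color or multi-channel PNG): ", path))
    }
    bd <- as.integer(info$bit.depth %||% 16L)
    px <- round(img * (2^bd - 1))
    return(raw_image(px, subject_id = sid, bit_depth = bd))
  }
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    if (length(dim(img)) == 3L) {
      abort(paste0("unsupported format (color or multi-channel TIFF): ", path))
    }
    bd <- as.integer(attr(img, "bits.per.sample") %||% 16L)
    return(raw_image(img, subject_id = sid, bit_depth = bd))
  }
  abort(paste0("unsupported image format: ", path))
}

#' Read a binary ROI mask
#'
#' Reads an 8-bit (or any grayscale) PNG/TIFF mask and binarizes it: any
#' nonzero pixel is foreground. The mask must match the paired image's
#' dimensions.
#'
#' @param path Path to the mask image.
#' @param image The paired [raw_image()] (for the dimension check), or `NULL`
#'   to skip the check.
#' @return An integer 0/1 matrix of class `roi_mask`.
#' @export
read_mask <- function(path, image = NULL) {
  if (!file.exists(path)) abort(paste0("cannot read mask, file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    abort(paste0("unsupported mask format: ", path))
  )
  if (length(dim(m)) == 3L) m <- m[, , 1]
  as_roi_mask(m, image = image, what = path)
}

#' Coerce a matrix to a binary ROI mask
#'
#' @param m Numeric or logical matrix; nonzero means foreground.
#' @inheritParams read_mask
#' @param what Label used in error messages.
#' @return Integer 0/1 matrix of class `roi_mask`.
#' @export
as_roi_mask <- function(m, image = NULL, what = "mask") {
  if (!is.matrix(m)) abort("mask must be a matrix")
  mask <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  if (!is.null(image) && !all(dim(mask) == dim(image$pixels))) {
    abort(sprintf("mask-mismatch: %s is %d x %d but image '%s' is %d x %d",
                  what, nrow(mask), ncol(mask),
                  image$subject_id, image$height, image$width))
  }
  structure(mask, class = c("roi_mask", "matrix", "array"))
}

#' Write a 16-bit grayscale image to disk
#'
#' Phantom slices are written as uncompressed 16-bit grayscale TIFF, which
#' round-trips integer pixel values exactly; masks as 8-bit PNG.
#'
#' @param image A [raw_image()].
#' @param path Destination path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Write a binary mask as 8-bit PNG
#'
#' @param mask A 0/1 matrix.
#' @param path Destination path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Write and read the per-subject feature table
#'
#' The feature table is the pipeline's tabular product: one row per subject
#' with the group label, the three first-order features, ROI bookkeeping
#' counts, and per-feature predicted labels. Values round-trip through CSV
#' at full double precision.
#'
#' @param features Tibble with at least columns `subject_id`, `group`,
#'   `mean`, `sd`, `entropy`, `n_roi`, `n_retained`.
#' @param path Destination CSV path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_feature_table <- function(features, path) {
  if (nrow(features) == 0L) abort("feature table is empty")
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(paste0("feature table not found: ", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("subject_id", "group", "mean", "sd", "entropy")
  missing <- setdiff(needed, names(tbl))
  if (length(missing)) {
    abort(paste0("feature table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl
}
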