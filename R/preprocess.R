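#' Dynamic gray-level scaling to 64 levels
#'
#' Quantizes the 12-bit intensity range (0--4095) to 64 gray levels (0--63)
#' by dropping the six least-significant bits: `out = floor(in / 64)`. This
#' concentrates the T2 histogram so that first-order texture statistics are
#' computed over a fixed 64-letter alphabet. The mapping is monotone
#' non-decreasing, sends 0 to 0 and 4095 to 63, and values above 4095 are
#' clipped (with a warning) before scaling.
#'
#' @param image A [raw_image()] or an integer matrix.
#' @return An object of class `scaled_image`: list with `pixels` (integer
#'   matrix in `[0, 63]`) and `subject_id`.
#' @export
scale_gray_levels <- function(image) {
  px <- if (inherits(image, "raw_image")) image$pixels else image
  sid <- if (inherits(image, "raw_image")) image$subject_id else "subject"
  if (!is.matrix(px)) abort("`image` must be a raw_image or a matrix")
  px <- matrix(as.integer(round(px)), nrow(px), ncol(px))
  if (any(px > 4095L)) {
    warn(sprintf("%d pixel(s) above 4095 clipped before gray-level scaling",
                 sum(px > 4095L)))
    px[px > 4095L] <- 4095L
  }
  if (any(px < 0L)) {
    warn("negative pixel(s) clipped to 0 before gray-level scaling")
    px[px < 0L] <- 0L
  }
  structure(list(pixels = px %/% 64L, subject_id = sid),
            class = "scaled_image")
}

#' Otsu's threshold on a set of gray levels
#'
#' Returns the cut point `k` in `[0, 62]` maximizing the between-class
#' variance `w0(k) * w1(k) * (mu0(k) - mu1(k))^2` of the split
#' `{v <= k}` vs `{v > k}` over values quantized to `[0, 63]`. Ties are
#' broken toward the smallest `k`. A constant input is degenerate: the
#' common value is returned with attribute `degenerate = TRUE`.
#'
#' @param values Integer vector of gray levels in `[0, 63]`.
#' @return Integer threshold level with logical attribute `degenerate`.
#' @export
otsu_threshold <- function(values) {
  if (length(values) == 0L) abort("empty-region: no values for Otsu thresholding")
  values <- as.integer(values)
  if (any(values < 0L | values > 63L)) {
    abort("Otsu thresholding expects scaled gray levels in [0, 63]")
  }
  counts <- tabulate(values + 1L, nbins = 64L)
  n <- length(values)
  if (sum(counts > 0L) == 1L) {
    return(structure(values[1L], degenerate = TRUE))
  }
  p <- counts / n
  levels <- 0:63
  w0 <- cumsum(p)[1:63]               # weight of class {v <= k}, k = 0..62
  m0 <- cumsum(p * levels)[1:63]      # unnormalized class-0 mean
  mt <- sum(p * levels)
  w1 <- 1 - w0
  sigma_b <- numeric(63)
  ok <- w0 > 0 & w1 > 0
  sigma_b[ok] <- (mt * w0[ok] - m0[ok])^2 / (w0[ok] * w1[ok])
  structure(which.max(sigma_b) - 1L, degenerate = FALSE)
}

#' Suppress vessels inside the ROI by Otsu thresholding
#'
#' Computes Otsu's threshold on the scaled gray levels inside the liver ROI
#' and removes the bright class (default), i.e. retains pixels with value
#' `<= level`. On T2-weighted TSE images the hepatic arteries, portal veins
#' and bile are hyperintense relative to parenchyma, so `side = "above"`
#' discards them; `side = "below"` retains the bright class instead. A
#' degenerate ROI (fewer than two distinct gray levels) is retained whole
#' with a warning.
#'
#' @param image A `scaled_image` (or integer matrix in `[0, 63]`).
#' @param roi A binary ROI matrix ([read_mask()] / [as_roi_mask()]).
#' @param side `"above"` (default) removes the bright class; `"below"`
#'   removes the dark class.
#' @return An object of class `retained_region`: list with `mask` (binary
#'   matrix, subset of `roi`), `values` (retained scaled intensities),
#'   `otsu_level`, `n_roi`, `n_retained`, `degenerate`.
#' @export
filter_vessels <- function(image, roi, side = c("above", "below")) {
  side <- match.arg(side)
  px <- if (inherits(image, "scaled_image")) image$pixels else image
  if (!is.matrix(px)) abort("`image` must be a scaled_image or a matrix")
  if (!all(dim(roi) == dim(px))) abort("mask-mismatch: ROI and image dimensions differ")
  inside <- roi != 0
  n_roi <- sum(inside)
  if (n_roi == 0L) abort("empty-region: ROI has no foreground pixels")
  vals <- px[inside]
  if (length(unique(vals)) < 2L) {
    warn("degenerate ROI (constant intensity): retaining all pixels")
    keep <- inside
    level <- vals[1L]
    degen <- TRUE
  } else {
    level <- otsu_threshold(vals)
    keep <- if (side == "above") inside & px <= level else inside & px > level
    degen <- FALSE
  }
  structure(
    list(mask = matrix(as.integer(keep), nrow(px), ncol(px)),
         values = px[keep],
         otsu_level = as.integer(level),
         n_roi = as.integer(n_roi),
         n_retained = as.integer(sum(keep)),
         degenerate = degen,
         side = side),
    class = "retained_region"
  )
}

#' @export
print.retained_region <- function(x, ...) {
  cat(sprintf("<retained_region> %d / %d ROI pixels retained (Otsu level %d, remove_%s%s)\n",
              x$n_retained, x$n_roi, x$otsu_level, x$side,
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}
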