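#' First-order texture features of the retained liver region
#'
#' Computes the three features used to quantify cirrhosis on the scaled
#' (0--63) intensities that survive vessel filtering:
#' * `mean` — arithmetic mean of retained gray levels;
#' * `sd` — sample standard deviation (n - 1 denominator), 0 for a single
#'   pixel (with a warning);
#' * `entropy` — Shannon entropy in bits of the 64-bin gray-level histogram,
#'   \eqn{-\sum_i p_i \log_2 p_i} with \eqn{0 \log 0 \equiv 0}; bounded by
#'   \eqn{\log_2 64 = 6}.
#'
#' Cirrhotic parenchyma is darker and more homogeneous on these T2 slices,
#' so all three features are expected to be smaller in the abnormal group.
#'
#' @param region A `retained_region` from [filter_vessels()], or an integer
#'   vector of gray levels in `[0, 63]`.
#' @return One-row tibble with columns `mean`, `sd`, `entropy`, `n_roi`,
#'   `n_retained`.
#' @export
compute_features <- function(region) {
  if (inherits(region, "retained_region")) {
    vals <- region$values
    n_roi <- region$n_roi
  } else {
    vals <- as.integer(region)
    n_roi <- length(vals)
  }
  n <- length(vals)
  if (n == 0L) abort("empty-region: no retained pixels to compute features on")
  if (any(vals < 0L | vals > 63L)) {
    abort("features are defined on scaled gray levels in [0, 63]")
  }
  if (n < 2L) {
    warn("single-pixel region: standard deviation set to 0")
    s <- 0
  } else {
    s <- stats::sd(vals)
  }
  p <- tabulate(vals + 1L, nbins = 64L) / n
  p <- p[p > 0]
  tibble(
    mean = base::mean(vals),
    sd = s,
    entropy = -sum(p * log2(p)),
    n_roi = as.integer(n_roi),
    n_retained = as.integer(n)
  )
}

#' Quantitative-value (QV) thresholds
#'
#' The per-feature operating thresholds read off the ROC's optimal point;
#' a subject is called abnormal on a feature when the feature value is less
#' than or equal to its QV. Defaults are the published cut-offs 2.8 (SD),
#' 0.7 (mean) and 0.3 (entropy).
#'
#' @param sd,mean,entropy Positive cut-offs in scaled-intensity units
#'   (entropy in bits).
#' @return Named numeric vector of class `qv_thresholds`.
#' @export
qv_thresholds <- function(sd = 2.8, mean = 0.7, entropy = 0.3) {
  qv <- c(sd = sd, mean = mean, entropy = entropy)
  if (any(!is.finite(qv)) || any(qv <= 0)) abort("QV thresholds must be positive")
  structure(qv, class = c("qv_thresholds", "numeric"))
}

#' Classify subjects by QV cut-offs
#'
#' Appends per-feature predicted labels to a feature table: a feature value
#' `f` with cut-off `q` is labelled `"abnormal"` iff `f <= q` (the boundary
#' is assigned to abnormal), else `"normal"`. Smaller mean, SD and entropy
#' indicate a higher probability of cirrhosis.
#'
#' @param features Tibble with columns `mean`, `sd`, `entropy`.
#' @param qv A [qv_thresholds()] vector.
#' @return `features` with added character columns `predicted_sd`,
#'   `predicted_mean`, `predicted_entropy`.
#' @export
classify_features <- function(features, qv = qv_thresholds()) {
  if (!all(c("mean", "sd", "entropy") %in% names(features))) {
    abort("feature table must have columns mean, sd, entropy")
  }
  dplyr::mutate(
    features,
    predicted_sd = ifelse(.data$sd <= qv[["sd"]], "abnormal", "normal"),
    predicted_mean = ifelse(.data$mean <= qv[["mean"]], "abnormal", "normal"),
    predicted_entropy = ifelse(.data$entropy <= qv[["entropy"]], "abnormal", "normal")
  )
}
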