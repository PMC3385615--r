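#' Confusion matrix for a binary diagnostic test
#'
#' Positive class is "abnormal" (cirrhotic) throughout.
#'
#' @param tp,fp,fn,tn Non-negative integer counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("confusion counts must be non-negative integers")
  }
  if (sum(counts) == 0) abort("empty-input: all-zero confusion matrix")
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fp = counts[2], fn = counts[3], tn = counts[4]),
            class = "confusion_matrix")
}

#' Build a confusion matrix from labels
#'
#' @param truth,predicted Character vectors of `"normal"` / `"abnormal"`.
#' @return A [confusion_counts()] object.
#' @export
confusion_from_labels <- function(truth, predicted) {
  if (length(truth) != length(predicted)) abort("truth and predicted lengths differ")
  lv <- c("normal", "abnormal")
  if (!all(truth %in% lv) || !all(predicted %in% lv)) {
    abort('labels must be "normal" or "abnormal"')
  }
  confusion_counts(
    tp = sum(truth == "abnormal" & predicted == "abnormal"),
    fp = sum(truth == "normal" & predicted == "abnormal"),
    fn = sum(truth == "abnormal" & predicted == "normal"),
    tn = sum(truth == "normal" & predicted == "normal")
  )
}

#' Performance rates from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy
#' `(tp+tn)/N`, PPV `tp/(tp+fp)` and NPV `tn/(tn+fn)`. A rate whose
#' denominator is zero is returned as `NA` with a warning rather than
#' silently as `NaN`.
#'
#' @param cm A [confusion_counts()] object.
#' @return One-row tibble with the five rates.
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  rate <- function(num, den, name) {
    if (den == 0) {
      warn(sprintf("%s undefined: zero denominator", name))
      return(NA_real_)
    }
    num / den
  }
  tibble(
    sensitivity = rate(cm$tp, cm$tp + cm$fn, "sensitivity"),
    specificity = rate(cm$tn, cm$tn + cm$fp, "specificity"),
    accuracy = (cm$tp + cm$tn) / (cm$tp + cm$fp + cm$fn + cm$tn),
    ppv = rate(cm$tp, cm$tp + cm$fp, "PPV"),
    npv = rate(cm$tn, cm$tn + cm$fn, "NPV")
  )
}

#' Cohen's kappa for diagnostic agreement
#'
#' Chance-corrected agreement \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with
#' observed agreement \eqn{p_o = (tp+tn)/N} and chance agreement
#' \eqn{p_e = [(tp+fp)(tp+fn) + (fn+tn)(fp+tn)]/N^2}. When both marginals
#' are concentrated in one class (`p_e = 1`) and agreement is perfect,
#' kappa is 1 by convention. With equal true-group sizes kappa reduces to
#' `2 * accuracy - 1`.
#'
#' @param cm A [confusion_counts()] object.
#' @return Numeric kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  po <- (cm$tp + cm$tn) / n
  pe <- ((cm$tp + cm$fp) * (cm$tp + cm$fn) +
           (cm$fn + cm$tn) * (cm$fp + cm$tn)) / n^2
  if (pe == 1) {
    if (po == 1) return(1)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' ROC curve with lower-value-is-positive orientation
#'
#' Because cirrhotic livers show *smaller* mean, SD and entropy, a subject
#' is called positive (abnormal) when its score is `<= t`. Thresholds are
#' the sorted unique scores plus `-Inf`/`Inf` sentinels; at threshold `t`,
#' sensitivity is the fraction of abnormal scores `<= t` and specificity
#' the fraction of normal scores `> t`. The AUC is the trapezoidal area
#' under (FPR, sensitivity), which equals the Mann-Whitney estimator
#' `P(abnormal < normal) + P(tie)/2`.
#'
#' @param scores_normal,scores_abnormal Numeric feature values per group.
#' @return Object of class `roc_curve`: list with `points` (tibble of
#'   `threshold`, `sensitivity`, `specificity`, `fpr`), `auc`, `direction`,
#'   group sizes.
#' @export
roc_curve <- function(scores_normal, scores_abnormal) {
  if (length(scores_normal) == 0L || length(scores_abnormal) == 0L) {
    abort("empty-group: both score groups must be non-empty")
  }
  if (anyNA(scores_normal) || anyNA(scores_abnormal)) {
    abort("ROC scores must not contain NA")
  }
  thr <- c(-Inf, sort(unique(c(scores_normal, scores_abnormal))), Inf)
  sens <- vapply(thr, function(t) base::mean(scores_abnormal <= t), numeric(1))
  spec <- vapply(thr, function(t) base::mean(scores_normal > t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
  structure(
    list(points = tibble(threshold = thr, sensitivity = sens,
                         specificity = spec, fpr = fpr),
         auc = auc,
         direction = "lower_is_positive",
         n_normal = length(scores_normal),
         n_abnormal = length(scores_abnormal)),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d abnormal vs %d normal, AUC = %.4f (lower score = positive)\n",
              x$n_abnormal, x$n_normal, x$auc))
  invisible(x)
}

#' Operating point of an ROC curve
#'
#' The quantitative value (QV) of a feature is read off the ROC's optimal
#' ("convex") point. The default rule maximizes Youden's
#' J = sensitivity + specificity - 1; `"closest_topleft"` minimizes the
#' Euclidean distance to the (FPR 0, sensitivity 1) corner. Ties are broken
#' toward the smallest threshold; the infinite sentinels are excluded.
#'
#' @param roc A [roc_curve()].
#' @param rule `"youden"` (default) or `"closest_topleft"`.
#' @return Numeric threshold (the QV).
#' @export
convex_point <- function(roc, rule = c("youden", "closest_topleft")) {
  rule <- match.arg(rule)
  pts <- roc$points[is.finite(roc$points$threshold), ]
  if (nrow(pts) == 0L) abort("degenerate ROC: no finite thresholds")
  crit <- switch(rule,
    youden = pts$sensitivity + pts$specificity - 1,
    closest_topleft = -((1 - pts$sensitivity)^2 + pts$fpr^2)
  )
  pts$threshold[which.max(crit)]
}

#' Significance of an AUC against the chance value 0.5
#'
#' Two-sided p-value from the normal approximation
#' `z = (auc - 0.5) / SE`, with the Hanley-McNeil standard error evaluated
#' under the null `auc = 0.5` (where `Q1 = Q2 = 1/3`):
#' `SE^2 = (A(1-A) + (n_a - 1)(Q1 - A^2) + (n_n - 1)(Q2 - A^2)) / (n_a n_n)`.
#'
#' @param auc AUC estimate in `[0, 1]`, or a [roc_curve()].
#' @param n_pos,n_neg Group sizes (abnormal, normal); taken from the curve
#'   when `auc` is a `roc_curve`.
#' @return Two-sided p-value.
#' @export
auc_significance <- function(auc, n_pos = NULL, n_neg = NULL) {
  if (inherits(auc, "roc_curve")) {
    n_pos <- n_pos %||% auc$n_abnormal
    n_neg <- n_neg %||% auc$n_normal
    auc <- auc$auc
  }
  if (is.null(n_pos) || is.null(n_neg) || n_pos < 2 || n_neg < 2) {
    abort("auc_significance needs group sizes >= 2")
  }
  a0 <- 0.5
  q <- 1 / 3
  se <- sqrt((a0 * (1 - a0) + (n_pos - 1) * (q - a0^2) +
                (n_neg - 1) * (q - a0^2)) / (n_pos * n_neg))
  z <- (auc - a0) / se
  p <- 2 * stats::pnorm(-abs(z))
  if ((auc == 0 || auc == 1) && (n_pos < 5 || n_neg < 5)) {
    warn("degenerate AUC with very small groups: normal-approximation p is crude")
  }
  p
}

#' Two-sample t-test from summary statistics or raw samples
#'
#' Pooled-variance (default) or Welch t-test computed directly from
#' `(mean, sd, n)` summaries, so published summary tables can be re-tested
#' without raw data. Raw numeric vectors are also accepted and reduced to
#' their summaries.
#'
#' @param a,b Either numeric vectors (raw samples) or lists/named vectors
#'   with elements `mean`, `sd`, `n`.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return One-row tibble with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  summ <- function(x) {
    if (is.numeric(x) && is.null(names(x)) && length(x) > 3) {
      list(mean = base::mean(x), sd = stats::sd(x), n = length(x))
    } else if (!is.null(names(x)) || is.list(x)) {
      x <- as.list(x)
      if (!all(c("mean", "sd", "n") %in% names(x))) {
        abort("summary input must have mean, sd, n")
      }
      x
    } else {
      list(mean = base::mean(x), sd = stats::sd(x), n = length(x))
    }
  }
  a <- summ(a); b <- summ(b)
  if (a$n < 2 || b$n < 2) abort("two_sample_t needs n >= 2 in both groups")
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean) {
    abort("undefined-t: zero variance in both groups with equal means")
  }
  if (variant == "pooled") {
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
    df <- a$n + b$n - 2
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- (a$mean - b$mean) / se
  tibble(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' 95% confidence interval for a mean from summary statistics
#'
#' `mean +/- t(0.975, n-1) * sd / sqrt(n)`.
#'
#' @param mean,sd,n Summary statistics (vectorized).
#' @return Tibble with columns `ci_low`, `ci_high`.
#' @export
ci95 <- function(mean, sd, n) {
  if (any(n < 2)) abort("insufficient-n: ci95 needs n >= 2")
  if (any(sd < 0)) abort("sd must be non-negative")
  half <- stats::qt(0.975, n - 1) * sd / sqrt(n)
  tibble(ci_low = mean - half, ci_high = mean + half)
}
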