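#' Evaluate a cohort's feature table against the diagnosis
#'
#' Assembles, per feature (sd, mean, entropy), the full diagnostic
#' evaluation: group summaries with 95% CIs, a two-sample t-test, the ROC
#' curve and AUC with its significance, the operating threshold (QV), the
#' confusion matrix at that QV, the five performance rates and Cohen's
#' kappa. Subjects are called abnormal on a feature when its value is
#' `<=` the QV.
#'
#' @param features Tibble with columns `group` (`"normal"`/`"abnormal"`)
#'   and `sd`, `mean`, `entropy` (one row per subject).
#' @param qv A [qv_thresholds()] vector, or `"auto"` to derive each QV from
#'   the ROC operating point.
#' @param operating_point Rule passed to [convex_point()] when `qv = "auto"`.
#' @param ttest `"pooled"` (default) or `"welch"`.
#' @return Object of class `cohort_evaluation`; see [tidy.cohort_evaluation()]
#'   and [glance.cohort_evaluation()].
#' @export
evaluate_cohort <- function(features, qv = qv_thresholds(),
                            operating_point = c("youden", "closest_topleft"),
                            ttest = c("pooled", "welch")) {
  operating_point <- match.arg(operating_point)
  ttest <- match.arg(ttest)
  needed <- c("group", "sd", "mean", "entropy")
  missing <- setdiff(needed, names(features))
  if (length(missing)) {
    abort(paste0("feature table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!all(features$group %in% c("normal", "abnormal"))) {
    abort('group labels must be "normal" or "abnormal"')
  }
  n_norm <- sum(features$group == "normal")
  n_abn <- sum(features$group == "abnormal")
  if (n_norm == 0L || n_abn == 0L) {
    abort("evaluation requires both a normal and an abnormal group")
  }
  auto_qv <- identical(qv, "auto")
  if (!auto_qv && !inherits(qv, "qv_thresholds")) {
    qv <- do.call(qv_thresholds, as.list(qv))
  }

  per_feature <- purrr::map(c(sd = "sd", mean = "mean", entropy = "entropy"), function(f) {
    x_norm <- features[[f]][features$group == "normal"]
    x_abn <- features[[f]][features$group == "abnormal"]
    if (anyNA(x_norm) || anyNA(x_abn)) {
      abort(sprintf("feature '%s' contains NA values", f))
    }
    summarize_group <- function(x) {
      ci <- ci95(base::mean(x), stats::sd(x), length(x))
      tibble(n = length(x), mean = base::mean(x), sd = stats::sd(x),
             ci_low = ci$ci_low, ci_high = ci$ci_high)
    }
    tt <- two_sample_t(x_norm, x_abn, variant = ttest)
    roc <- roc_curve(x_norm, x_abn)
    threshold <- if (auto_qv) convex_point(roc, rule = operating_point) else qv[[f]]
    predicted <- ifelse(features[[f]] <= threshold, "abnormal", "normal")
    cm <- confusion_from_labels(features$group, predicted)
    list(
      feature = f,
      normal = summarize_group(x_norm),
      abnormal = summarize_group(x_abn),
      t_test = tt,
      roc = roc,
      qv = threshold,
      confusion = cm,
      rates = confusion_metrics(cm),
      kappa = cohen_kappa(cm),
      auc = roc$auc,
      auc_p = auc_significance(roc)
    )
  })

  structure(
    list(per_feature = per_feature,
         qv_mode = if (auto_qv) "auto" else "fixed",
         operating_point = operating_point,
         ttest = ttest,
         n_normal = n_norm,
         n_abnormal = n_abn),
    class = "cohort_evaluation"
  )
}

#' Tidy a cohort evaluation
#'
#' One row per feature with the QV, performance rates, kappa, AUC and
#' test statistics — the package's analogue of a published performance
#' table.
#'
#' @param x A `cohort_evaluation`.
#' @param ... Unused.
#' @return A tibble with one row per feature.
#' @exportS3Method generics::tidy
tidy.cohort_evaluation <- function(x, ...) {
  purrr::map_dfr(x$per_feature, function(f) {
    tibble(
      feature = f$feature,
      qv = f$qv,
      sensitivity = f$rates$sensitivity,
      specificity = f$rates$specificity,
      accuracy = f$rates$accuracy,
      ppv = f$rates$ppv,
      npv = f$rates$npv,
      kappa = f$kappa,
      auc = f$auc,
      auc_p = f$auc_p,
      t = f$t_test$t,
      df = f$t_test$df,
      t_p = f$t_test$p,
      mean_normal = f$normal$mean,
      mean_abnormal = f$abnormal$mean,
      ci_low_normal = f$normal$ci_low,
      ci_high_normal = f$normal$ci_high,
      ci_low_abnormal = f$abnormal$ci_low,
      ci_high_abnormal = f$abnormal$ci_high
    )
  })
}

#' One-line summary of a cohort evaluation
#'
#' @param x A `cohort_evaluation`.
#' @param ... Unused.
#' @return One-row tibble with cohort sizes and the AUC range.
#' @exportS3Method generics::glance
glance.cohort_evaluation <- function(x, ...) {
  aucs <- purrr::map_dbl(x$per_feature, "auc")
  tibble(
    n_normal = x$n_normal,
    n_abnormal = x$n_abnormal,
    n_features = length(x$per_feature),
    qv_mode = x$qv_mode,
    min_auc = min(aucs),
    max_auc = max(aucs)
  )
}

#' @export
print.cohort_evaluation <- function(x, ...) {
  cat(sprintf("Cohort evaluation: %d normal vs %d abnormal subjects (QV %s)\n\n",
              x$n_normal, x$n_abnormal, x$qv_mode))
  tbl <- tidy(x)
  show <- tbl[, c("feature", "qv", "sensitivity", "specificity", "accuracy",
                  "ppv", "npv", "kappa", "auc")]
  show[-1] <- lapply(show[-1], function(v) round(v, 3))
  print(as.data.frame(show), row.names = FALSE)
  cat("\nGroup means (normal vs abnormal), pooled-t p-values:\n")
  for (f in x$per_feature) {
    cat(sprintf("  %-8s %.3f vs %.3f  (p = %.3g)\n",
                f$feature, f$normal$mean, f$abnormal$mean, f$t_test$p))
  }
  invisible(x)
}

#' Write a cohort evaluation as a JSON report
#'
#' Per-feature blocks mirror the evaluation surface: group summaries with
#' 95% CIs, t-test, QV, confusion counts, rates, kappa, AUC and its
#' p-value.
#'
#' @param evaluation A `cohort_evaluation`.
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(evaluation, path) {
  stopifnot(inherits(evaluation, "cohort_evaluation"))
  blocks <- purrr::map(evaluation$per_feature, function(f) {
    list(
      qv = f$qv,
      normal = as.list(f$normal),
      abnormal = as.list(f$abnormal),
      t_test = as.list(f$t_test),
      confusion = unclass(f$confusion),
      rates = as.list(f$rates),
      kappa = f$kappa,
      auc = f$auc,
      auc_p_value = f$auc_p
    )
  })
  report <- list(
    n_normal = evaluation$n_normal,
    n_abnormal = evaluation$n_abnormal,
    qv_mode = evaluation$qv_mode,
    operating_point = evaluation$operating_point,
    t_test_variant = evaluation$ttest,
    features = blocks
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
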