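#' Quantify a single liver slice
#'
#' The per-subject pipeline: dynamic gray-level scaling to 64 levels,
#' ROI-restricted Otsu vessel filtering, and first-order feature
#' extraction.
#'
#' @param image A [raw_image()].
#' @param mask A binary ROI matrix.
#' @param vessel_side Passed to [filter_vessels()].
#' @return List with `features` (one-row tibble) and `region` (the
#'   `retained_region`).
#' @export
quantify_slice <- function(image, mask, vessel_side = "above") {
  scaled <- scale_gray_levels(image)
  region <- filter_vessels(scaled, mask, side = vessel_side)
  list(features = compute_features(region), region = region)
}

#' Extract features for a cohort
#'
#' Runs the per-subject pipeline over a cohort table, classifies each
#' subject against the QV cut-offs, and returns the feature table. A
#' subject whose image or mask cannot be processed gets a `status` message
#' and `NA` features; the run continues.
#'
#' @param cohort Tibble with columns `subject_id`, `group`, `image`,
#'   `mask` (file paths), e.g. from [generate_cohort()] or a cohort CSV.
#' @param qv A [qv_thresholds()] vector used for per-subject labels.
#' @param vessel_side Passed to [filter_vessels()].
#' @param verbose Log per-subject Otsu level and retained counts to stderr.
#' @return Feature tibble: `subject_id`, `group`, `mean`, `sd`, `entropy`,
#'   `n_roi`, `n_retained`, `otsu_level`, `status`, and per-feature
#'   `predicted_*` labels.
#' @export
extract_features <- function(cohort, qv = qv_thresholds(),
                             vessel_side = "above", verbose = FALSE) {
  needed <- c("subject_id", "group", "image", "mask")
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    abort(paste0("cohort table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  rows <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    rec <- cohort[i, ]
    res <- tryCatch({
      img <- read_image(rec$image, subject_id = rec$subject_id)
      msk <- read_mask(rec$mask, image = img)
      out <- quantify_slice(img, msk, vessel_side = vessel_side)
      if (verbose) {
        message(sprintf("[%s] otsu=%d retained=%d/%d",
                        rec$subject_id, out$region$otsu_level,
                        out$region$n_retained, out$region$n_roi))
      }
      dplyr::mutate(out$features,
                    subject_id = rec$subject_id, group = rec$group,
                    otsu_level = out$region$otsu_level,
                    status = "ok", .before = 1)
    }, error = function(e) {
      warn(sprintf("subject %s failed: %s", rec$subject_id, conditionMessage(e)))
      tibble(subject_id = rec$subject_id, group = rec$group,
             otsu_level = NA_integer_, status = paste0("failed: ", conditionMessage(e)),
             mean = NA_real_, sd = NA_real_, entropy = NA_real_,
             n_roi = NA_integer_, n_retained = NA_integer_)
    })
    res
  })
  ok <- rows$status == "ok"
  out <- rows
  pred_cols <- c("predicted_sd", "predicted_mean", "predicted_entropy")
  out[pred_cols] <- NA_character_
  if (any(ok)) {
    preds <- classify_features(rows[ok, c("mean", "sd", "entropy")], qv = qv)
    out[ok, pred_cols] <- preds[pred_cols]
  }
  out
}
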