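#' Parameters for synthetic T2-like liver phantoms
#'
#' The phantom emulates the statistical structure the pipeline exploits: an
#' elliptical "liver" filled with spatially correlated Gaussian texture on a
#' noisy background, with bright circular "vessels" inside the ROI. The
#' abnormal group uses a lower parenchyma level and a smaller texture SD
#' than the normal group, so after 64-level scaling its mean, SD and entropy
#' are all smaller — the cirrhotic ordering. All levels are raw 12-bit
#' intensity units in `[0, 4095]`.
#'
#' @param size Image height and width in pixels.
#' @param center,semi_axes Liver ellipse center (row, col) and semi-axes
#'   (row, col) in pixels; the ellipse must fit inside the image.
#' @param background_level,background_sd Background intensity and Gaussian
#'   noise SD.
#' @param normal_level,normal_sd Parenchyma base level and texture SD for
#'   the normal group.
#' @param abnormal_level,abnormal_sd Same for the abnormal (cirrhotic)
#'   group — darker and more homogeneous.
#' @param correlation_length Gaussian smoothing sigma (pixels) giving the
#'   texture its spatial correlation.
#' @param n_vessels Number of circular vessels placed inside the ROI.
#' @param vessel_radius Inclusive (min, max) vessel radius range in pixels.
#' @param vessel_level Vessel intensity; must exceed each group's
#'   `level + 3 * sd` so Otsu can separate vessels from parenchyma.
#' @return Validated list of class `phantom_params`.
#' @export
phantom_params <- function(size = c(128L, 128L),
                           center = c(64, 64),
                           semi_axes = c(44, 30),
                           background_level = 100,
                           background_sd = 20,
                           normal_level = 900,
                           normal_sd = 160,
                           abnormal_level = 300,
                           abnormal_sd = 40,
                           correlation_length = 2,
                           n_vessels = 5L,
                           vessel_radius = c(1, 3),
                           vessel_level = 3500) {
  p <- list(size = as.integer(size), center = center, semi_axes = semi_axes,
            background_level = background_level, background_sd = background_sd,
            normal_level = normal_level, normal_sd = normal_sd,
            abnormal_level = abnormal_level, abnormal_sd = abnormal_sd,
            correlation_length = correlation_length,
            n_vessels = as.integer(n_vessels),
            vessel_radius = vessel_radius, vessel_level = vessel_level)
  lv <- c(p$background_level, p$normal_level, p$abnormal_level, p$vessel_level)
  if (any(lv < 0 | lv > 4095)) abort("phantom levels must lie in [0, 4095]")
  for (g in c("normal", "abnormal")) {
    if (p$vessel_level <= p[[paste0(g, "_level")]] + 3 * p[[paste0(g, "_sd")]]) {
      abort(sprintf("vessel level must exceed %s parenchyma level + 3 * sd", g))
    }
  }
  if (any(p$center - p$semi_axes < 1) ||
      any(p$center + p$semi_axes > p$size)) {
    abort("liver ellipse does not fit inside the image")
  }
  if (p$n_vessels < 0 || p$vessel_radius[1] > p$vessel_radius[2] ||
      p$vessel_radius[1] < 0) {
    abort("invalid vessel parameters")
  }
  structure(p, class = "phantom_params")
}

# Separable Gaussian blur with edge replication; sigma in pixels.
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(mat) {
    top <- mat[rep(1L, r), , drop = FALSE]
    bot <- mat[rep(nrow(mat), r), , drop = FALSE]
    padded <- rbind(top, mat, bot)
    out <- apply(padded, 2, function(col) stats::filter(col, k, sides = 2))
    out[(r + 1L):(r + nrow(mat)), , drop = FALSE]
  }
  t(pad_conv(t(pad_conv(m))))
}

#' Generate one synthetic phantom subject
#'
#' Deterministic given `(params, group, seed)`. The parenchyma texture is a
#' white Gaussian field smoothed with a Gaussian kernel and rescaled to the
#' group's base level and SD; vessels are circular discs set to the vessel
#' level at random positions strictly inside the ROI. All values are clipped
#' to `[0, 4095]` and rounded to integers.
#'
#' @param params A [phantom_params()].
#' @param group `"normal"` or `"abnormal"`.
#' @param seed Integer seed.
#' @param subject_id Optional id; defaults to `"<group>_<seed>"`.
#' @return List of class `phantom_subject` with elements `image`
#'   ([raw_image()]), `roi` (`roi_mask`), `vessel_mask`, `group`, `seed`.
#' @export
generate_phantom <- function(params = phantom_params(),
                             group = c("normal", "abnormal"),
                             seed = 1L, subject_id = NULL) {
  group <- match.arg(group)
  if (!inherits(params, "phantom_params")) abort("params must be phantom_params()")
  h <- params$size[1]; w <- params$size[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  a <- params$semi_axes[1]; b <- params$semi_axes[2]
  ed2 <- ((rows - params$center[1]) / a)^2 + ((cols - params$center[2]) / b)^2
  roi <- ed2 <= 1

  level <- params[[paste0(group, "_level")]]
  tex_sd <- params[[paste0(group, "_sd")]]

  out <- withr::with_seed(as.integer(seed), {
    img <- matrix(rnorm(h * w, params$background_level, params$background_sd), h, w)
    field <- gaussian_smooth(matrix(rnorm(h * w), h, w),
                             params$correlation_length)
    field <- (field - base::mean(field)) / stats::sd(field)
    img[roi] <- level + tex_sd * field[roi]

    vmask <- matrix(FALSE, h, w)
    if (params$n_vessels > 0L) {
      placed <- 0L
      tries <- 0L
      while (placed < params$n_vessels && tries < 1000L) {
        tries <- tries + 1L
        r <- runif(1, params$vessel_radius[1], params$vessel_radius[2])
        cy <- runif(1, params$center[1] - a, params$center[1] + a)
        cx <- runif(1, params$center[2] - b, params$center[2] + b)
        # require the whole disc inside the ellipse (conservative bound)
        margin2 <- ((rows - cy)^2 + (cols - cx)^2) <= r^2
        if (!any(margin2)) next
        if (all(ed2[margin2] <= (1 - (r + 1) / min(a, b))^2)) {
          vmask <- vmask | margin2
          placed <- placed + 1L
        }
      }
      img[vmask] <- params$vessel_level
    }
    list(img = img, vmask = vmask)
  })

  px <- pmin(pmax(round(out$img), 0), 4095)
  sid <- subject_id %||% paste0(group, "_", seed)
  structure(
    list(image = raw_image(px, subject_id = sid, bit_depth = 12L),
         roi = as_roi_mask(roi),
         vessel_mask = as_roi_mask(out$vmask & roi),
         group = group,
         seed = as.integer(seed)),
    class = "phantom_subject"
  )
}

#' Generate a phantom cohort on disk
#'
#' Writes `n_normal + n_abnormal` phantom slices (16-bit TIFF) and ROI masks
#' (8-bit PNG) with per-subject seeds `seed + index`, plus a cohort CSV.
#' Defaults reproduce a 31 + 31 cohort.
#'
#' @param params A [phantom_params()].
#' @param n_normal,n_abnormal Group sizes.
#' @param seed Master seed; subject `i` uses `seed + i`.
#' @param dir Output directory (created if needed).
#' @return Cohort tibble with columns `subject_id`, `group`, `image`,
#'   `mask`, `seed`; also written to `<dir>/cohort.csv`.
#' @export
generate_cohort <- function(params = phantom_params(), n_normal = 31L,
                            n_abnormal = 31L, seed = 1L, dir) {
  if (n_normal < 1L || n_abnormal < 1L) abort("cohort group sizes must be >= 1")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    abort(paste0("cannot create output directory: ", dir))
  }
  groups <- c(rep("normal", n_normal), rep("abnormal", n_abnormal))
  cohort <- purrr::map_dfr(seq_along(groups), function(i) {
    g <- groups[i]
    sid <- sprintf("%s_%02d", g, if (g == "normal") i else i - n_normal)
    subj <- generate_phantom(params, group = g, seed = as.integer(seed) + i,
                             subject_id = sid)
    img_path <- file.path(dir, paste0(sid, ".tif"))
    mask_path <- file.path(dir, paste0(sid, "_mask.png"))
    write_image(subj$image, img_path)
    write_mask(subj$roi, mask_path)
    tibble(subject_id = sid, group = g, image = img_path, mask = mask_path,
           seed = as.integer(seed) + i)
  })
  readr::write_csv(cohort, file.path(dir, "cohort.csv"))
  cohort
}

#' Run the full pipeline on in-memory phantom subjects
#'
#' Convenience for simulation studies: generates a cohort of phantom
#' subjects and extracts their features without touching the filesystem.
#'
#' @inheritParams generate_cohort
#' @param vessel_side Passed to [filter_vessels()].
#' @return Feature tibble as from [extract_features()] (plus a
#'   `vessel_removed_frac` column: fraction of true vessel pixels removed).
#' @export
simulate_cohort_features <- function(params = phantom_params(), n_normal = 31L,
                                     n_abnormal = 31L, seed = 1L,
                                     vessel_side = "above") {
  groups <- c(rep("normal", n_normal), rep("abnormal", n_abnormal))
  purrr::map_dfr(seq_along(groups), function(i) {
    g <- groups[i]
    subj <- generate_phantom(params, group = g, seed = as.integer(seed) + i)
    res <- quantify_slice(subj$image, subj$roi, vessel_side = vessel_side)
    n_vessel <- sum(subj$vessel_mask)
    removed_frac <- if (n_vessel == 0L) NA_real_ else {
      retained <- res$region$mask
      1 - sum(retained[subj$vessel_mask == 1L]) / n_vessel
    }
    dplyr::mutate(res$features,
                  subject_id = subj$image$subject_id, group = g,
                  otsu_level = res$region$otsu_level,
                  vessel_removed_frac = removed_frac,
                  .before = 1)
  })
}
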