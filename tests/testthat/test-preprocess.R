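test_that("gray-level scaling is floor(v/64) over the whole 12-bit range", {
  all_in <- matrix(0:4095, 64, 64)
  out <- scale_gray_levels(all_in)$pixels
  expect_identical(as.vector(out), as.integer(floor(0:4095 / 64)))
  expect_equal(range(out), c(0L, 63L))
  # endpoints of the stated ranges
  expect_equal(out[1], 0L)
  expect_equal(out[4096], 63L)
  # monotone non-decreasing along the input order
  expect_true(all(diff(as.vector(out)) >= 0))
  # spot values around the first bin edges
  expect_identical(scale_gray_levels(matrix(c(63L, 64L, 127L, 128L), 1))$pixels[1, ],
                   c(0L, 1L, 1L, 2L))
})

test_that("out-of-range values are clipped with a warning", {
  expect_warning(s <- scale_gray_levels(matrix(c(0L, 5000L), 1, 2)), "clipped")
  expect_identical(s$pixels[1, ], c(0L, 63L))
  expect_true(all(scale_gray_levels(matrix(0L, 3, 3))$pixels == 0L))
})

test_that("scaling inverts multiplication by 64 on already-scaled images", {
  withr::local_seed(13)
  s <- matrix(sample(0:63, 100, replace = TRUE), 10, 10)
  expect_identical(scale_gray_levels(s * 64L)$pixels, s)
})

test_that("Otsu threshold equals the exhaustive between-class-variance argmax", {
  withr::local_seed(17)
  # clearly bimodal case: cut must separate 2s from 60s
  vals <- c(rep(2L, 50), rep(60L, 50))
  k <- otsu_threshold(vals)
  expect_true(k >= 2L && k <= 59L)
  expect_equal(as.integer(k), oracle_otsu(vals))

  # random instances, several shapes
  for (i in 1:50) {
    n <- sample(20:200, 1)
    vals <- switch(1 + (i %% 3),
      sample(0:63, n, replace = TRUE),
      pmin(63L, pmax(0L, round(c(rnorm(n / 2, 15, 4), rnorm(n / 2, 45, 6))))),
      pmin(63L, rpois(n, 20))
    )
    expect_equal(as.integer(otsu_threshold(vals)), oracle_otsu(vals),
                 info = paste("instance", i))
  }
})

test_that("constant input is flagged degenerate and returns its own level", {
  k <- otsu_threshold(rep(7L, 25))
  expect_equal(as.integer(k), 7L)
  expect_true(attr(k, "degenerate"))
  expect_error(otsu_threshold(integer(0)), "empty-region")
  expect_error(otsu_threshold(c(1L, 99L)), "\\[0, 63\\]")
})

test_that("vessel filtering removes the bright class and conserves pixels", {
  px <- matrix(0L, 20, 20)
  roi <- matrix(0L, 20, 20)
  roi[3:17, 3:17] <- 1L
  in_roi <- which(roi == 1L)
  px[in_roi] <- 2L
  px[in_roi[1:10]] <- 60L  # 10 bright "vessel" pixels among 225
  reg <- filter_vessels(px, roi)
  expect_equal(reg$n_roi, 225L)
  expect_equal(reg$n_retained, 215L)
  expect_true(all(reg$values == 2L))
  expect_true(reg$otsu_level >= 2L && reg$otsu_level < 60L)
  # conservation and subset invariants
  expect_equal(reg$n_retained + sum(px[roi == 1L] > reg$otsu_level), reg$n_roi)
  expect_true(all(reg$mask[roi == 0L] == 0L))
  # retained values are exactly the ROI values <= level
  expect_setequal(reg$values, px[roi == 1L][px[roi == 1L] <= reg$otsu_level])
})

test_that("remove_below retains the bright class instead", {
  px <- matrix(0L, 10, 10)
  roi <- matrix(1L, 10, 10)
  px[1:50] <- 3L
  px[51:100] <- 55L
  reg <- filter_vessels(px, roi, side = "below")
  expect_true(all(reg$values == 55L))
  expect_equal(reg$n_retained, 50L)
})

test_that("degenerate and empty ROIs follow the contract", {
  px <- matrix(5L, 8, 8)
  roi <- matrix(1L, 8, 8)
  expect_warning(reg <- filter_vessels(px, roi), "degenerate")
  expect_equal(reg$n_retained, reg$n_roi)
  expect_true(reg$degenerate)
  expect_error(filter_vessels(px, matrix(0L, 8, 8)), "empty-region")
  expect_error(filter_vessels(px, matrix(1L, 4, 4)), "mask-mismatch")
})

test_that("known phantom vessels are removed from the ROI", {
  subj <- generate_phantom(group = "normal", seed = 99)
  scaled <- scale_gray_levels(subj$image)
  reg <- filter_vessels(scaled, subj$roi)
  v <- sum(subj$vessel_mask)
  expect_gt(v, 0)
  removed <- subj$roi == 1L & reg$mask == 0L
  expect_gte(sum(removed[subj$vessel_mask == 1L]) / v, 0.99)
})
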