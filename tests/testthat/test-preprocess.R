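# geometric and intensity preprocessing

test_that("resample_to_grid: identity, constants, and a naive oracle", {
  img <- matrix(rnorm(40 * 30), 40, 30)
  out <- resample_to_grid(img, 0.5, 0.5)
  expect_identical(out$image, img)

  cons <- matrix(3.5, 20, 20)
  out <- resample_to_grid(cons, 1, 0.5)
  expect_identical(dim(out$image), c(40L, 40L))
  expect_true(all(abs(out$image - 3.5) < 1e-12))

  # bilinear interpolation of a plane is exact away from the clamped border
  ramp <- outer(0:19, 0:14, function(i, j) 2 * i - 3 * j + 1)
  up <- resample_to_grid(ramp, 1, 0.5)$image
  down <- resample_to_grid(up, 0.5, 1)$image
  expect_lt(max(abs(down[1:18, 1:13] - ramp[1:18, 1:13])), 1e-9)

  # naive oracle at arbitrary target spacing
  out <- resample_to_grid(ramp, 1, 0.7)$image
  naive <- matrix(0, nrow(out), ncol(out))
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    u <- min((i - 1) * 0.7, 19); v <- min((j - 1) * 0.7, 14)
    i0 <- min(floor(u), 18); j0 <- min(floor(v), 13)
    fu <- u - i0; fv <- v - j0
    naive[i, j] <- (1 - fu) * (1 - fv) * ramp[i0 + 1, j0 + 1] +
      fu * (1 - fv) * ramp[i0 + 2, j0 + 1] +
      (1 - fu) * fv * ramp[i0 + 1, j0 + 2] + fu * fv * ramp[i0 + 2, j0 + 2]
  }
  expect_lt(max(abs(out - naive)), 1e-12)
  expect_error(resample_to_grid(img, -1, 0.5), class = "radpt_input_error")
})

test_that("mask resampling stays binary and preserves containment", {
  cfg <- phantom_config(n_patients = 1, seed = 2, pixel_spacing = 1,
                        image_size = 48)
  st <- generate_study(cfg, 1)
  pro <- resample_to_grid(st$prostate_mask, 1, 0.5, "nearest")$image
  les <- resample_to_grid(st$lesions[[1]]$mask, 1, 0.5, "nearest")$image
  expect_type(pro, "logical")
  expect_true(all(pro[les]))
  # nearest ties at .5 round toward the lower index
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  out <- resample_to_grid(m, 1, 0.5, "nearest")$image
  expect_equal(out[2, 2], m[1, 1])  # coordinate 0.5 -> index 0
})

test_that("interpolate_slices matches closed-form linear interpolation", {
  cons <- array(2, dim = c(4, 4, 6))
  out <- interpolate_slices(cons, 1.5, 3)
  expect_true(all(out$volume == 2))
  expect_true(abs(dim(out$volume)[3] - 3) <= 1)

  ramp <- array(rep(0:5, each = 16), dim = c(4, 4, 6))
  out <- interpolate_slices(ramp, 2, 3)$volume
  for (k in seq_len(dim(out)[3])) {
    w <- (k - 1) * 3 / 2
    expect_equal(out[1, 1, k], min(w, 5), tolerance = 1e-12)
  }
  expect_warning(interpolate_slices(array(1, c(2, 2, 1)), 3, 3),
                 "single-slice")
})

test_that("z-score standardization: moments and affine invariance", {
  set.seed(3)
  img <- array(rnorm(16 * 16 * 3, 100, 20), dim = c(16, 16, 3))
  mask <- array(FALSE, dim = dim(img)); mask[4:12, 4:12, ] <- TRUE
  z <- standardize_intensity(img, mask, "zscore_in_prostate")
  expect_lt(abs(mean(z[mask])), 1e-9)
  expect_lt(abs(sd(z[mask]) - 1), 1e-9)
  z2 <- standardize_intensity(2.5 * img + 17, mask, "zscore_in_prostate")
  expect_lt(max(abs(z - z2)), 1e-9)
  expect_error(standardize_intensity(array(1, dim(img)), mask,
                                     "zscore_in_prostate"),
               class = "radpt_degenerate_error")
  expect_error(standardize_intensity(img, array(FALSE, dim(img))),
               class = "radpt_input_error")
})

test_that("landmark standardization aligns scanner-gain pairs", {
  set.seed(4)
  img <- array(rgamma(20 * 20 * 2, 4, 0.05), dim = c(20, 20, 2))
  mask <- array(TRUE, dim = dim(img))
  a <- standardize_intensity(img, mask, "histogram_landmarks")
  b <- standardize_intensity(1.8 * img + 30, mask, "histogram_landmarks")
  da <- quantile(a[mask], (1:9) / 10)
  db <- quantile(b[mask], (1:9) / 10)
  expect_lt(max(abs(da - db)) / sd(a[mask]), 0.05)
  # monotone in input
  o <- order(img[mask])
  expect_true(all(diff(a[mask][o]) >= -1e-12))
})

test_that("crop_to_roi geometry and exact round-trip", {
  img <- matrix(rnorm(30 * 30), 30, 30)
  all_mask <- matrix(TRUE, 30, 30)
  out <- crop_to_roi(img, all_mask, 2, 0.5)
  expect_identical(out$image, img)
  expect_identical(out$offset, c(0L, 0L))

  one <- matrix(FALSE, 30, 30); one[11, 11] <- TRUE  # 0-based (10, 10)
  out <- crop_to_roi(img, one, 2, 0.5)
  expect_identical(dim(out$image), c(9L, 9L))  # 4-pixel pad each side
  expect_identical(out$offset, c(6L, 6L))

  blank <- matrix(0, 30, 30)
  back <- paste_from_crop(blank, out$image, out$offset)
  expect_identical(back[7:15, 7:15], img[7:15, 7:15])
  expect_error(crop_to_roi(img, matrix(FALSE, 30, 30), 2, 0.5),
               class = "radpt_input_error")
})

test_that("preprocessed study keeps mask containment and unit variance", {
  st <- fixture_study()
  expect_true(all(st$prostate_mask[st$lesions[[1]]$mask]))
  expect_lt(abs(sd(st$t2w[st$prostate_mask]) - 1), 1e-9)
  expect_lt(abs(mean(st$adc[st$prostate_mask])), 1e-9)
})
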