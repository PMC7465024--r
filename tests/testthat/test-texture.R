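# texture operators vs naive oracles and analytic cases

test_that("quantize_image handles constants, two-point data, uniform fill", {
  cons <- matrix(5, 6, 6)
  q <- quantize_image(cons, matrix(TRUE, 6, 6), 8)
  expect_true(all(q == 0))
  two <- matrix(c(1, 9), 4, 4)
  q <- quantize_image(two, matrix(TRUE, 4, 4), 2)
  expect_setequal(unique(as.vector(q)), c(0L, 1L))
  set.seed(1)
  u <- matrix(runif(80 * 80), 80, 80)
  q <- quantize_image(u, matrix(TRUE, 80, 80), 64)
  p <- chisq.test(table(factor(q, 0:63)))$p.value
  expect_gt(p, 0.01)
})

test_that("glcm matches exhaustive pair enumeration", {
  cons <- matrix(0L, 4, 4)
  P <- glcm(cons, n_levels = 4)
  expect_equal(P[1, 1], 1)
  expect_equal(sum(P), 1)

  chk <- outer(1:6, 1:6, function(i, j) (i + j) %% 2L)
  P <- glcm(chk, offsets = rbind(c(0L, 1L)), n_levels = 2)
  expect_equal(P[1, 1] + P[2, 2], 0)  # checkerboard: all mass off-diagonal

  set.seed(2)
  q <- matrix(sample(0:4, 25, TRUE), 5, 5)
  P <- glcm(q, n_levels = 5)
  # brute-force ordered pair count over the 4 offsets, both directions
  cnt <- matrix(0, 5, 5)
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    for (i in 1:5) for (j in 1:5) {
      ii <- i + off[1]; jj <- j + off[2]
      if (ii >= 1 && ii <= 5 && jj >= 1 && jj <= 5) {
        a <- q[i, j]; b <- q[ii, jj]
        cnt[a + 1, b + 1] <- cnt[a + 1, b + 1] + 1
        cnt[b + 1, a + 1] <- cnt[b + 1, a + 1] + 1
      }
    }
  }
  expect_equal(P, cnt / sum(cnt))
  expect_error(glcm(matrix(0L, 1, 1), n_levels = 2),
               class = "radpt_empty_pairs")
})

test_that("haralick_stats: analytic values and literal-formula oracle", {
  single <- matrix(0, 4, 4); single[1, 1] <- 1
  h <- haralick_stats(single)
  expect_equal(h[["energy"]], 1)
  expect_equal(h[["entropy"]], 0)
  expect_equal(h[["contrast"]], 0)

  L <- 8
  uni <- matrix(1 / L^2, L, L)
  expect_equal(haralick_stats(uni)[["entropy"]], 2 * log(L))

  set.seed(3)
  for (r in 1:5) {
    A <- matrix(rexp(36), 6, 6); A <- A + t(A); A <- A / sum(A)
    expect_equal(haralick_stats(A), literal_haralick(A), tolerance = 1e-10)
  }
})

test_that("haralick_maps agree with a naive per-pixel reimplementation", {
  set.seed(4)
  img <- matrix(rnorm(16 * 16), 16, 16)
  mask <- matrix(FALSE, 16, 16); mask[3:14, 4:13] <- TRUE
  maps <- haralick_maps(img, mask, window_sizes = c(3, 5), n_levels = 8)
  for (px in list(c(5, 6), c(8, 9), c(3, 4), c(14, 13))) {
    for (wi in 1:2) {
      w <- c(3, 5)[wi]
      ref <- naive_haralick_pixel(img, mask, px[1], px[2], w, 8)
      got <- maps[px[1], px[2], (wi - 1) * 13 + 1:13]
      expect_equal(unname(got), unname(ref), tolerance = 1e-8)
    }
  }
  expect_true(all(is.na(maps[1, 1, ])))  # outside ROI
  # constant image: energy map 1, entropy map 0 inside the ROI
  mcon <- haralick_maps(matrix(7, 10, 10), matrix(TRUE, 10, 10), 3, 8)
  expect_true(all(mcon[, , "w3_energy"] == 1))
  expect_true(all(mcon[, , "w3_entropy"] == 0))
  expect_error(haralick_maps(img, mask, window_sizes = 4),
               class = "radpt_input_error")
})

test_that("gabor bank: size, zero DC, unit norm, matched-filter response", {
  bank <- gabor_bank()
  expect_length(bank, 76)
  for (k in bank[c(1, 20, 76)]) {
    expect_lt(abs(sum(k)), 1e-12)
    expect_equal(sum(k^2), 1, tolerance = 1e-12)
  }
  expect_error(gabor_bank(wavelengths = c(3, 4), n_orientations = 5),
               class = "radpt_config_error")
  # constant image -> all responses 0
  resp <- gabor_maps(matrix(4, 32, 32), bank)
  expect_lt(max(abs(resp)), 1e-9)
  # grating at (lambda = 4, theta = 0): matched filter beats orthogonal
  ij <- outer(0:47, rep(1, 48))
  grating <- cos(2 * pi * ij / 4)
  resp <- gabor_maps(grating, bank)
  matched <- mean(abs(resp[10:38, 10:38, "l4o00"]))
  ortho <- mean(abs(resp[10:38, 10:38, sprintf("l4o%02d", 9)]))
  expect_gt(matched, ortho * 5)
  # linearity of convolution
  set.seed(5)
  x <- matrix(rnorm(24 * 24), 24, 24)
  r1 <- gabor_maps(x, bank[1:3])
  r2 <- gabor_maps(3 * x, bank[1:3])
  expect_equal(r2, 3 * r1, tolerance = 1e-9)
})

test_that("gabor FFT path equals direct reflect-padded correlation", {
  set.seed(6)
  img <- matrix(rnorm(30 * 37), 30, 37)
  bank <- gabor_bank()
  got <- gabor_maps(img, bank)
  for (k in c(1, 40, 76))
    expect_equal(got[, , k], radpt:::.conv2_reflect_cpp(img, bank[[k]]),
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("laws kernels: count, zero sums, analytic ramp response", {
  ker <- laws_kernels()
  expect_length(ker, 25)
  sums <- vapply(ker, sum, numeric(1))
  expect_equal(unname(sums["L5L5"]), 256)
  expect_true(all(abs(sums[names(sums) != "L5L5"]) < 1e-12))
  cons <- laws_maps(matrix(2, 12, 12))
  expect_true(all(abs(cons[, , "E5L5"]) < 1e-9))
  expect_true(all(abs(cons[, , "L5L5"] - 512) < 1e-9))
  # vertical ramp img[i, j] = s * i: E5L5 interior response = 128 * s
  s <- 0.75
  ramp <- outer(1:15, rep(1, 15)) * s
  m <- laws_maps(ramp)
  expect_equal(unname(m[5:11, 5:11, "E5L5"]),
               matrix(128 * s, 7, 7), tolerance = 1e-9)
  # naive conv oracle on a random image
  set.seed(7)
  x <- matrix(rnorm(12 * 12), 12, 12)
  m <- laws_maps(x)
  expect_equal(m[, , "S5R5"], naive_conv2_reflect(x, ker$S5R5),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("first-order maps match naive window statistics", {
  cons <- matrix(3, 10, 10)
  fo <- first_order_maps(cons, matrix(TRUE, 10, 10))
  expect_true(all(fo$maps[, , "mean3"] == 3))
  expect_true(all(fo$maps[, , "median5"] == 3))
  expect_true(all(fo$maps[, , "sd3"] == 0))
  expect_true(all(fo$maps[, , "range3"] == 0))
  expect_true(all(abs(fo$maps[, , "sobelmag"]) < 1e-12))
  expect_equal(fo$signal, 3)

  # ramp: Sobel row-gradient is constant, proportional to the slope
  ramp <- outer(1:12, rep(1, 12)) * 2
  fo <- first_order_maps(ramp, matrix(TRUE, 12, 12))
  expect_true(all(abs(fo$maps[2:11, 2:11, "sobelx"] - 16) < 1e-9))
  expect_true(all(abs(fo$maps[2:11, 2:11, "sobely"]) < 1e-9))

  set.seed(8)
  x <- matrix(rnorm(14 * 14), 14, 14)
  fo <- first_order_maps(x, matrix(TRUE, 14, 14))
  for (px in list(c(1, 1), c(7, 8), c(14, 14), c(2, 13))) {
    ref3 <- naive_window_stats(x, 3, px[1], px[2])
    ref5 <- naive_window_stats(x, 5, px[1], px[2])
    expect_equal(unname(fo$maps[px[1], px[2], "mean3"]), ref3$mean)
    expect_equal(unname(fo$maps[px[1], px[2], "median3"]), ref3$median)
    expect_equal(unname(fo$maps[px[1], px[2], "sd3"]), ref3$sd)
    expect_equal(unname(fo$maps[px[1], px[2], "range3"]), ref3$range)
    expect_equal(unname(fo$maps[px[1], px[2], "mean5"]), ref5$mean)
    expect_equal(unname(fo$maps[px[1], px[2], "median5"]), ref5$median)
  }
})

test_that("collage: orientation eigen-oracle, constant-gradient entropy", {
  # globally constant gradient direction -> entropy ~ 0 in the interior
  ramp <- outer(1:24, 1:24, function(i, j) 2 * i + 3 * j)
  mask <- matrix(FALSE, 24, 24); mask[5:20, 5:20] <- TRUE
  cm <- collage_maps(ramp, mask)
  expect_lt(max(abs(cm[8:17, 8:17, "w5_entropy"])), 1e-6)

  # per-pixel dominant orientation vs an independent eigen decomposition
  set.seed(9)
  img <- matrix(rnorm(20 * 20), 20, 20)
  th <- collage_orientation(img, 5)
  sk <- radpt:::.conv2_reflect_cpp
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  gx <- sk(img, kx); gy <- sk(img, t(kx))
  for (px in list(c(7, 7), c(10, 14), c(15, 5))) {
    i <- px[1]; j <- px[2]
    ii <- (i - 2):(i + 2); jj <- (j - 2):(j + 2)
    G <- cbind(as.vector(gx[ii, jj]), as.vector(gy[ii, jj]))
    ev <- eigen(crossprod(G))$vectors[, 1]
    ang <- atan2(ev[2], ev[1]) %% pi
    diff <- abs(th[i, j] - ang) %% pi
    expect_lt(min(diff, pi - diff), 1e-8)
  }

  # rotating the image by 90 degrees leaves the entropy map invariant
  # (up to the transposed geometry) in the interior
  rot <- t(img)[ncol(img):1, ]
  m_all <- matrix(TRUE, 20, 20)
  e1 <- collage_maps(img, m_all)[, , "w5_entropy"]
  e2 <- collage_maps(rot, m_all)[, , "w5_entropy"]
  e2_back <- t(e2[nrow(e2):1, ])
  expect_equal(e1[6:15, 6:15], e2_back[6:15, 6:15], tolerance = 1e-8)
})

test_that("aggregate_map moments", {
  cons <- matrix(2.5, 5, 5)
  m <- matrix(TRUE, 5, 5)
  expect_equal(aggregate_map(cons, m, "mean"), 2.5)
  expect_equal(aggregate_map(cons, m, "sd"), 0)
  set.seed(10)
  z <- rnorm(1e5)
  expect_equal(aggregate_map(z, NULL, "kurtosis"), 3, tolerance = 0.1)
  expect_equal(aggregate_map(z, NULL, "skewness"), 0, tolerance = 0.05)
  expect_true(is.na(aggregate_map(cons, matrix(FALSE, 5, 5), "mean")))
})

test_that("extract_all honours the battery count contracts", {
  ft <- fixture_features()
  fc <- feature_cols(ft)
  info <- parse_feature_name(fc)
  counts <- table(info$sequence, info$roi)
  expect_true(all(counts == 150))          # 150 per sequence per ROI
  expect_equal(sum(info$roi == "IT"), 300) # IT across both sequences
  expect_equal(sum(info$roi != "IT"), 1200)
  expect_equal(sum(info$family == "gabor"), 76 * 2 * 5)
  expect_equal(sum(info$family == "haralick"), 39 * 2 * 5)
  expect_equal(sum(info$family == "laws"), 25 * 2 * 5)
  expect_equal(sum(info$family == "fo"), 9 * 2 * 5)
  expect_equal(sum(info$family == "signal"), 1 * 2 * 5)
  # no missing values on non-empty ROIs; all finite here
  expect_true(all(is.finite(as.matrix(ft[, fc]))))
  # collage extension adds 13 per sequence per ROI
  b <- texture_battery("default", include_collage = TRUE)
  expect_equal(nrow(b), 163)
  # multiple aggregators multiply the column count
  b_mini <- texture_battery("mini")
  st <- fixture_study()
  ft2 <- extract_all(st, battery = b_mini,
                     aggregators = c("mean", "sd"))
  expect_equal(length(feature_cols(ft2)), nrow(b_mini) * 2 * 5 * 2)
})

test_that("texture features are invariant to pre-standardization shifts", {
  cfg <- phantom_config(n_patients = 1, seed = 77, n_slices_range = c(3, 3))
  st <- generate_study(cfg, 1)
  st_shift <- st
  st_shift$t2w <- st$t2w + 123
  st_shift$adc <- st$adc + 0.7
  a <- extract_all(preprocess_study(st), battery = "mini")
  b <- extract_all(preprocess_study(st_shift), battery = "mini")
  fc <- feature_cols(a)
  expect_equal(as.numeric(a[1, fc]), as.numeric(b[1, fc]),
               tolerance = 1e-8)
})

test_that("feature names round-trip through the parser", {
  nm <- feature_name("ADC", "PT_6_9", "haralick", "w7_sum_entropy", "mean")
  info <- parse_feature_name(nm)
  expect_equal(info$roi, "PT_6_9")
  expect_equal(info$param, "w7_sum_entropy")
  expect_error(parse_feature_name("bad.name"), class = "radpt_input_error")
})
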