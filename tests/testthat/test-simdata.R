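# phantom cohort generator

test_that("generate_study is deterministic and structurally valid", {
  cfg <- phantom_config(n_patients = 3, seed = 9)
  st <- generate_study(cfg, 2)
  expect_identical(st, generate_study(cfg, 2))
  expect_s3_class(st, "radpt_study")
  expect_identical(dim(st$t2w), dim(st$adc))
  expect_identical(dim(st$t2w), dim(st$prostate_mask))
  for (l in st$lesions) {
    expect_type(l$mask, "logical")
    expect_true(all(st$prostate_mask[l$mask]))  # lesion inside prostate
    expect_true(l$risk %in% c("L", "I", "H"))
    expect_true(l$pirads %in% 1:5)
  }
  # a different patient index gives a different study
  expect_false(identical(st$t2w, generate_study(cfg, 1)$t2w))
})

test_that("generate_cohort bookkeeping and manifest determinism", {
  cfg <- phantom_config(n_patients = 5, seed = 3)
  co <- generate_cohort(cfg)
  expect_length(co$studies, 5)
  expect_identical(nrow(co$manifest),
                   sum(vapply(co$studies, function(s) length(s$lesions), 1L)))
  expect_identical(co$manifest, generate_cohort(cfg)$manifest)
  # different seed: different manifest, same schema
  co2 <- generate_cohort(phantom_config(n_patients = 5, seed = 4))
  expect_identical(names(co2$manifest), names(co$manifest))
  expect_false(identical(co$manifest$risk, co2$manifest$risk) &&
                 identical(co$manifest$pirads, co2$manifest$pirads) &&
                 identical(co$manifest$n_slices, co2$manifest$n_slices))
  # RDS + CSV artifacts
  dir <- withr::local_tempdir()
  generate_cohort(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_length(list.files(dir, pattern = "\\.rds$"), 5)
})

test_that("class mix converges to the configured proportions", {
  # scaled down from the design-scale check (300 patients, +/-0.08) to
  # keep the suite fast: ~60 patients, a correspondingly wider binomial band
  cfg <- phantom_config(n_patients = 60, seed = 21,
                        n_slices_range = c(3, 3),
                        lesion_thickness_factor = c(0.3, 0.5))
  man <- generate_cohort(cfg)$manifest
  freq <- table(factor(man$risk, c("L", "I", "H"))) / nrow(man)
  expect_true(all(abs(freq - 1 / 3) < 0.15))
})

test_that("assign_pirads maps risk classes and honours the noise level", {
  set.seed(1)
  expect_true(all(replicate(50, assign_pirads("H", 0)) %in% 4:5))
  expect_true(all(replicate(50, assign_pirads("L", 0)) %in% 1:2))
  expect_identical(assign_pirads("I", 0), 3L)
  expect_error(assign_pirads("X", 0), class = "radpt_input_error")
  expect_error(assign_pirads("L", 1.5), class = "radpt_input_error")
  # full noise: uniform over 1..5 (chi-squared at alpha = 0.01)
  draws <- replicate(1e4, assign_pirads("H", 1))
  p <- chisq.test(table(factor(draws, 1:5)))$p.value
  expect_gt(p, 0.01)
})

test_that("lesion ADC mean decreases with risk under a -3 SD shift", {
  # scaled-down Monte-Carlo of the design contract (design scale: 200
  # cohorts of 50 patients, >= 95% ordering)
  ok <- vapply(1:15, function(s) {
    cfg <- phantom_config(n_patients = 10, seed = 100 + s,
                          adc_shift = c(L = 0, I = -1.5, H = -3),
                          class_mix = c(L = 0.5, I = 0, H = 0.5),
                          n_slices_range = c(3, 3))
    co <- generate_cohort(cfg)
    vals <- lapply(co$studies, function(st)
      lapply(st$lesions, function(l)
        data.frame(risk = l$risk, adc = mean(st$adc[l$mask]))))
    df <- do.call(rbind, unlist(vals, recursive = FALSE))
    has <- all(c("L", "H") %in% df$risk)
    !has || mean(df$adc[df$risk == "H"]) < mean(df$adc[df$risk == "L"])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("infeasible lesion geometry is rejected", {
  expect_error(phantom_config(prostate_axes_mm = c(4, 4),
                              lesion_radius_mm = c(5, 6)),
               class = "radpt_geometry_error")
  expect_error(phantom_config(class_mix = c(L = 0.5, I = 0.2, H = 0.2)),
               class = "radpt_config_error")
  expect_error(phantom_config(image_size = 40),
               class = "radpt_config_error")
})

test_that("null-effect configuration yields identically distributed classes", {
  # with all effects zero, lesion-masked summary statistics must not differ
  # systematically between classes (checked loosely via a rank-sum test on
  # pooled lesion means over several cohorts)
  vals <- list()
  for (s in 1:6) {
    cfg <- phantom_config_null(n_patients = 8, seed = 300 + s,
                               class_mix = c(L = 0.5, I = 0, H = 0.5),
                               n_slices_range = c(3, 3))
    co <- generate_cohort(cfg)
    for (st in co$studies) for (l in st$lesions)
      vals[[length(vals) + 1]] <- data.frame(risk = l$risk,
                                             m = mean(st$t2w[l$mask]))
  }
  df <- do.call(rbind, vals)
  p <- ranksum_test(df$m[df$risk == "L"], df$m[df$risk == "H"])$p.value
  expect_gt(p, 0.01)
})
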