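# QDA, grouped cross-validation, hold-out protocol

test_that("qda_fit separates well-separated clouds and recovers parameters", {
  set.seed(1)
  X <- rbind(matrix(rnorm(200, 0), 100, 2),
             matrix(rnorm(200, 4), 100, 2))
  y <- rep(0:1, each = 100)
  m <- qda_fit(X, y)
  acc <- mean((qda_score(m, X) > 0) == (y == 1))
  expect_gte(acc, 0.95)

  # parameter recovery on a large sample (within 2%)
  n <- 1e5
  S <- matrix(c(2, 0.6, 0.6, 1), 2)
  Z <- matrix(rnorm(2 * n), n, 2) %*% chol(S)
  X2 <- rbind(Z, sweep(matrix(rnorm(2 * n), n, 2), 2, c(3, -1), `+`))
  y2 <- rep(0:1, each = n)
  m2 <- qda_fit(X2, y2, shrinkage = 0)
  expect_equal(unname(m2$fits[[1]]$cov), S, tolerance = 0.02)
  expect_equal(unname(m2$fits[[2]]$mean), c(3, -1), tolerance = 0.02)
  expect_equal(m2$fits[[1]]$prior, 0.5)
  expect_error(qda_fit(X[1:3, ], c(0, 0, 0)), class = "radpt_input_error")
})

test_that("QDA with equal class covariances reduces exactly to LDA", {
  set.seed(2)
  X0 <- matrix(rnorm(120), 60, 2)
  X1 <- sweep(X0, 2, c(2, 1), `+`)   # exact covariance copy, shifted
  X <- rbind(X0, X1); y <- rep(0:1, each = 60)
  m <- qda_fit(X, y, shrinkage = 0)
  sc <- qda_score(m, X)
  # closed-form LDA discriminant with the (equal) ML covariance
  S <- m$fits[[1]]$cov
  mu0 <- m$fits[[1]]$mean; mu1 <- m$fits[[2]]$mean
  w <- solve(S, mu1 - mu0)
  b <- -0.5 * sum((mu1 + mu0) * w)
  ref <- X %*% w + b                  # equal priors -> no prior term
  expect_equal(unname(sc), unname(as.vector(ref)), tolerance = 1e-8)
})

test_that("qda_score equals a direct Gaussian density oracle", {
  set.seed(3)
  X <- rbind(matrix(rnorm(100, 0, 1.3), 50, 2),
             matrix(rnorm(100, 1.5), 50, 2))
  y <- rep(0:1, each = 50)
  m <- qda_fit(X, y, shrinkage = 1e-3)
  sc <- qda_score(m, X)
  logdens <- function(x, mu, S)
    -0.5 * log(det(2 * pi * S)) -
      0.5 * drop(t(x - mu) %*% solve(S) %*% (x - mu))
  ref <- apply(X, 1, function(x)
    logdens(x, m$fits[[2]]$mean, m$fits[[2]]$cov) + log(m$fits[[2]]$prior) -
      logdens(x, m$fits[[1]]$mean, m$fits[[1]]$cov) - log(m$fits[[1]]$prior))
  expect_equal(unname(sc), unname(ref), tolerance = 1e-8)
})

test_that("1-D midpoint: score crosses zero halfway between the means", {
  # means 0 and 2, unit ML variances, equal priors
  m <- qda_fit(matrix(c(-1, 1, 1, 3), 4, 1), c(0, 0, 1, 1), shrinkage = 0)
  expect_equal(qda_score(m, matrix(1, 1, 1)), 0, tolerance = 1e-12)
  expect_gt(qda_score(m, matrix(2, 1, 1)), 0)
  expect_lt(qda_score(m, matrix(0, 1, 1)), 0)
})

test_that("simulated AUC approaches the closed form Phi(Delta/sqrt(2))", {
  set.seed(4)
  n <- 1e4
  delta <- 1
  scores <- c(rnorm(n), rnorm(n, delta))
  labels <- rep(0:1, each = n)
  expect_equal(roc_auc(scores, labels)$auc, pnorm(delta / sqrt(2)),
               tolerance = 0.02)
})

test_that("cross_validate: grouped folds, stratification, determinism", {
  tab <- fixture_labelled_table(n_patients = 24, seed = 7)
  # add a second lesion for some patients to exercise the grouping
  extra <- tab[1:6, ]
  extra$lesion_id <- sub("L1", "L2", extra$lesion_id)
  tab2 <- rbind(tab, extra)
  y <- as.integer(tab2$risk == "H")
  feats <- c("T2W.IT.fo.mean3.mean", "ADC.IT.signal.raw.mean")
  cv <- cross_validate(tab2, y, tab2$patient_id, feats,
                       runs = 10, folds = 3, seed = 5)
  expect_equal(nrow(cv), 30)
  # no patient straddles train/test in any fold
  for (run in seq_len(10)) {
    fo <- attr(cv, "fold_assignments")[[run]]
    expect_false(any(is.na(fo)))
    by_pat <- tapply(fo[tab2$patient_id], tab2$patient_id,
                     function(v) length(unique(v)))
    expect_true(all(by_pat == 1))
  }
  expect_gt(attr(cv, "mean_auc"), 0.6)   # informative features
  cv2 <- cross_validate(tab2, y, tab2$patient_id, feats,
                        runs = 10, folds = 3, seed = 5)
  expect_identical(cv, cv2)

  # 9 single-lesion patients, one run: folds of exactly {3, 3, 3}
  tab9 <- fixture_labelled_table(n_patients = 9, seed = 8)
  y9 <- as.integer(tab9$risk == "H")
  cv9 <- cross_validate(tab9, y9, tab9$patient_id, feats,
                        runs = 1, folds = 3, seed = 1)
  sizes <- table(attr(cv9, "fold_assignments")[[1]])
  expect_true(all(sizes == 3))
})

test_that("null labels give chance-level cross-validated AUC", {
  set.seed(9)
  aucs <- vapply(1:10, function(s) {
    tab <- fixture_labelled_table(n_patients = 40, seed = 100 + s)
    # destroy the signal: labels are re-drawn independently of features
    y <- rbinom(nrow(tab), 1, 0.5)
    if (length(unique(y)) < 2) return(NA_real_)
    feats <- feature_cols(tab)[1:4]
    cv <- cross_validate(tab, y, tab$patient_id, feats,
                         runs = 5, folds = 3, seed = s)
    attr(cv, "mean_auc")
  }, numeric(1))
  expect_lt(abs(mean(aucs, na.rm = TRUE) - 0.5), 0.1)
})

test_that("fit_and_holdout enforces patient disjointness and is deterministic", {
  tab <- fixture_labelled_table(n_patients = 40, seed = 11)
  d1 <- tab[1:20, ]; d2 <- tab[21:40, ]
  y1 <- as.integer(d1$risk == "H"); y2 <- as.integer(d2$risk == "H")
  feats <- c("T2W.IT.fo.mean3.mean", "ADC.IT.signal.raw.mean")
  ho <- fit_and_holdout(d1, d2, y1, y2, feats)
  expect_gt(ho$auc_d2, 0.7)            # planted signal transfers
  expect_identical(ho$scores_d2,
                   fit_and_holdout(d1, d2, y1, y2, feats)$scores_d2)
  expect_error(fit_and_holdout(d1, rbind(d2, d1[1, ]), y1, c(y2, y1[1]),
                               feats),
               class = "radpt_leakage_error")
})
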