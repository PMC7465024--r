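#' Fit a quadratic discriminant analysis model
#'
#' Class means and covariances are maximum-likelihood estimates (n
#' denominator); priors are class frequencies. Each covariance is
#' regularized by shrinkage toward a scaled identity:
#' `(1 - gamma) * Sigma + gamma * (trace(Sigma) / d) * I`.
#'
#' @param X numeric matrix (samples x features)
#' @param y binary labels (0/1 or two-level factor); class 1 is positive
#' @param shrinkage shrinkage weight gamma in `[0, 1]`
#' @return a `qda_model`: per-class priors, means, covariances; feature
#'   names are order-locked
#' @export
qda_fit <- function(X, y, shrinkage = 1e-3) {
  X <- as.matrix(X)
  y <- as.integer(as.factor(y)) - 1L
  if (length(unique(y)) != 2)
    stop_radpt("radpt_input_error", "y must have exactly two classes")
  d <- ncol(X)
  classes <- c(0L, 1L)
  fit_one <- function(k) {
    Xi <- X[y == k, , drop = FALSE]
    n <- nrow(Xi)
    if (n < 2)
      stop_radpt("radpt_input_error", "need >= 2 samples per class")
    mu <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mu)
    S <- crossprod(Xc) / n
    S <- (1 - shrinkage) * S + shrinkage * (sum(diag(S)) / d) * diag(d)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch))
      stop_radpt("radpt_illconditioned",
                 "singular class covariance after shrinkage")
    list(prior = n / nrow(X), mean = mu, cov = S, chol = ch,
         logdet = 2 * sum(log(diag(ch))))
  }
  structure(list(classes = classes,
                 fits = lapply(classes, fit_one),
                 features = colnames(X), shrinkage = shrinkage),
            class = "qda_model")
}

#' Positive-class QDA score (log posterior odds)
#'
#' `score = log p(x | 1) + log pi_1 - log p(x | 0) - log pi_0`, monotone in
#' the posterior probability of the positive class; 0 is the posterior-0.5
#' operating point.
#'
#' @param model a [qda_fit()] model
#' @param X matrix with columns in the model's feature order
#' @return numeric vector of scores
#' @export
qda_score <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$fits[[1]]$mean))
    stop_radpt("radpt_input_error", "feature dimension mismatch")
  if (!is.null(model$features) && !is.null(colnames(X)) &&
      !identical(colnames(X), model$features))
    X <- X[, model$features, drop = FALSE]
  disc <- function(fit) {
    Z <- backsolve(fit$chol, t(sweep(X, 2, fit$mean)), transpose = TRUE)
    -0.5 * colSums(Z^2) - 0.5 * fit$logdet + log(fit$prior)
  }
  disc(model$fits[[2]]) - disc(model$fits[[1]])
}

# z-normalization parameters estimated on training data only
zfit <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mean = mu, sd = s)
}
zapply <- function(X, z) sweep(sweep(as.matrix(X), 2, z$mean), 2, z$sd, `/`)

# patient-level class = maximum-risk lesion of the patient
patient_strata <- function(patients, y) {
  vapply(split(y, patients), max, numeric(1))
}

#' Patient-grouped repeated stratified cross-validation of a QDA model
#'
#' D1-style evaluation: patients (never lesions) are split into `folds`
#' folds, stratified by the patient's maximum-risk class; all lesions of a
#' patient share a fold. In each of `runs` repetitions each fold serves
#' once as the test set; features are z-normalized with training-fold
#' parameters. Folds whose training part lacks a class, or whose test part
#' is single-class, are resampled (logged via `attr(, "resampled")`).
#'
#' @param table feature table rows (already restricted to the feature pool)
#' @param y binary labels (1 = positive)
#' @param patient_groups patient id per row
#' @param features feature columns to use (order-locked)
#' @param runs,folds repetition and fold counts
#' @param seed RNG seed for the fold draws
#' @param shrinkage QDA covariance shrinkage
#' @return a `cv_result`: data.frame (`run`, `fold`, `auc`, `n_test`) plus
#'   attributes `mean_auc`, `sd_auc`, `fold_assignments`
#' @export
cross_validate <- function(table, y, patient_groups, features,
                           runs = 100, folds = 3, seed = 1,
                           shrinkage = 1e-3) {
  X <- as.matrix(table[, features, drop = FALSE])
  pats <- unique(patient_groups)
  strata <- patient_strata(patient_groups, y)[pats]
  if (min(table(strata)) < folds && length(unique(strata)) > 1)
    warning("fewer patients than folds in a stratum; stratification is best-effort")
  res <- vector("list", runs * folds)
  assignments <- vector("list", runs)
  resampled <- 0L
  with_seed(seed, {
    for (run in seq_len(runs)) {
      for (attempt in 1:25) {
        fold_of <- rep(NA_integer_, length(pats))
        names(fold_of) <- pats
        offset <- 0L
        for (s in unique(strata)) {
          ps <- pats[strata == s]
          ps <- ps[sample.int(length(ps))]
          # rotate the starting fold across strata so total fold sizes
          # stay balanced to within one patient
          fold_of[ps] <- (seq_along(ps) - 1L + offset) %% folds + 1L
          offset <- (offset + length(ps)) %% folds
        }
        ok <- TRUE
        for (f in seq_len(folds)) {
          test <- patient_groups %in% pats[fold_of == f]
          if (length(unique(y[!test])) < 2 ||
              length(unique(y[test])) < 2) { ok <- FALSE; break }
        }
        if (ok) break
        resampled <- resampled + 1L
      }
      assignments[[run]] <- fold_of
      for (f in seq_len(folds)) {
        test <- patient_groups %in% pats[fold_of == f]
        z <- zfit(X[!test, , drop = FALSE])
        model <- qda_fit(zapply(X[!test, , drop = FALSE], z), y[!test],
                         shrinkage)
        sc <- qda_score(model, zapply(X[test, , drop = FALSE], z))
        auc <- if (length(unique(y[test])) < 2) NA_real_
               else roc_auc(sc, y[test])$auc
        res[[(run - 1) * folds + f]] <-
          data.frame(run = run, fold = f, auc = auc, n_test = sum(test))
      }
    }
  })
  out <- do.call(rbind, res)
  attr(out, "mean_auc") <- mean(out$auc, na.rm = TRUE)
  attr(out, "sd_auc") <- stats::sd(out$auc, na.rm = TRUE)
  attr(out, "fold_assignments") <- assignments
  attr(out, "resampled") <- resampled
  class(out) <- c("cv_result", "data.frame")
  out
}

#' Train on all of D1, score the held-out D2
#'
#' The leakage protocol of the analysis: feature selection must have used
#' D1 only; z-normalization parameters and the QDA fit come from all of D1
#' and are applied unchanged to D2. Any patient overlap between the
#' cohorts is a protocol violation.
#'
#' @param table_d1,table_d2 feature tables (training / hold-out)
#' @param y1,y2 binary labels (1 = positive)
#' @param features feature columns (typically a selection result's
#'   features, order-locked)
#' @param shrinkage QDA covariance shrinkage
#' @return list with `model`, `scores_d2`, `auc_d2`, `scores_d1`, `auc_d1`
#' @export
fit_and_holdout <- function(table_d1, table_d2, y1, y2, features,
                            shrinkage = 1e-3) {
  if (length(intersect(unique(table_d1$patient_id),
                       unique(table_d2$patient_id))))
    stop_radpt("radpt_leakage_error",
               "patient overlap between training and hold-out cohorts")
  X1 <- as.matrix(table_d1[, features, drop = FALSE])
  X2 <- as.matrix(table_d2[, features, drop = FALSE])
  z <- zfit(X1)
  model <- qda_fit(zapply(X1, z), y1, shrinkage)
  s1 <- qda_score(model, zapply(X1, z))
  s2 <- qda_score(model, zapply(X2, z))
  list(model = model, normalization = z,
       scores_d1 = s1, auc_d1 = roc_auc(s1, y1)$auc,
       scores_d2 = s2, auc_d2 = roc_auc(s2, y2)$auc)
}
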