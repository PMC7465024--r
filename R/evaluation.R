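#' ROC curve and AUC
#'
#' Thresholds sweep the sorted unique scores; the area is the trapezoidal
#' integral of TPR over FPR, which equals the Mann-Whitney concordance
#' probability `U / (n1 * n0)` with half-credit for tied score pairs.
#'
#' @param scores numeric scores (larger = more positive)
#' @param labels binary labels (1 = positive)
#' @return a `roc_result`: list with `thresholds`, `tpr`, `fpr`, `auc`
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop_radpt("radpt_input_error", "AUC undefined: single-class labels")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & labels == 1) / n1,
                numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & labels == 0) / n0,
                numeric(1))
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = th, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_result")
}

#' Binarize PI-RADS v2 scores
#'
#' Scores 1-2 map to "low", 3-5 to "high" likelihood of clinically
#' significant cancer.
#'
#' @param scores integer vector with values in 1..5
#' @return character vector of "low"/"high", order preserved
#' @export
binarize_pirads <- function(scores) {
  if (any(!scores %in% 1:5))
    stop_radpt("radpt_input_error", "PI-RADS scores must be in 1..5")
  ifelse(scores >= 3, "high", "low")
}

#' Risk stratification cross-tabulation and accuracies
#'
#' Cross-tabulates the three-level D'Amico risk category against a binary
#' high/low prediction for each method (e.g., binarized PI-RADS and the
#' thresholded radiomic score). Per-class accuracies are
#' correct-high / total-high and correct-low / total-low; the overall
#' accuracy counts correctly classified high- and low-risk lesions over
#' ALL lesions including intermediates (the convention recoverable from
#' the published arithmetic, e.g. 79/150 = 53%).
#'
#' @param drcs_labels vector of "H"/"I"/"L" (or "High"/...)
#' @param ... named binary prediction vectors ("high"/"low"), one per
#'   method, each aligned with `drcs_labels`
#' @return a `stratification_table`: list with `counts` (3 x 2 per
#'   method), `accuracy` (per method: high, low, overall), `n`
#' @export
stratification_table <- function(drcs_labels, ...) {
  preds <- list(...)
  if (!length(preds)) stop_radpt("radpt_input_error", "no predictions")
  lab <- toupper(substr(as.character(drcs_labels), 1, 1))
  if (!all(lab %in% c("H", "I", "L")))
    stop_radpt("radpt_input_error", "risk labels must be H/I/L")
  n <- length(lab)
  counts <- list(); acc <- list()
  for (m in names(preds)) {
    p <- tolower(as.character(preds[[m]]))
    if (length(p) != n)
      stop_radpt("radpt_input_error", "prediction length mismatch for %s", m)
    if (!all(p %in% c("high", "low")))
      stop_radpt("radpt_input_error", "predictions must be high/low")
    tab <- matrix(0L, 3, 2,
                  dimnames = list(c("High", "Intermediate", "Low"),
                                  c("High", "Low")))
    for (r in 1:3) {
      rl <- c("H", "I", "L")[r]
      tab[r, 1] <- sum(lab == rl & p == "high")
      tab[r, 2] <- sum(lab == rl & p == "low")
    }
    counts[[m]] <- tab
    acc[[m]] <- c(
      high = tab["High", "High"] / sum(tab["High", ]),
      low = tab["Low", "Low"] / sum(tab["Low", ]),
      overall = (tab["High", "High"] + tab["Low", "Low"]) / n)
  }
  structure(list(counts = counts, accuracy = acc, n = n,
                 row_totals = rowSums(counts[[1]])),
            class = "stratification_table")
}

#' @export
print.stratification_table <- function(x, ...) {
  for (m in names(x$counts)) {
    cat(sprintf("== %s ==\n", m))
    print(cbind(x$counts[[m]], Total = rowSums(x$counts[[m]])))
    cat(sprintf("accuracy: high %.1f%%, low %.1f%%, overall %.1f%%\n",
                100 * x$accuracy[[m]]["high"], 100 * x$accuracy[[m]]["low"],
                100 * x$accuracy[[m]]["overall"]))
  }
  invisible(x)
}

# restrict a feature table to a pool (IT / PT / IT+PT) and sequence set
pool_columns <- function(table, pool = c("IT_PT", "IT", "PT"),
                         sequences = c("T2W", "ADC")) {
  pool <- match.arg(pool)
  if (identical(sequences, "both")) sequences <- c("T2W", "ADC")
  info <- parse_feature_name(feature_cols(table))
  keep <- info$sequence %in% sequences
  if (pool == "IT") keep <- keep & info$roi == "IT"
  if (pool == "PT") keep <- keep & info$roi != "IT"
  feature_cols(table)[keep]
}

#' AUC report across feature pools, sequences, settings and cohorts
#'
#' For every combination of feature pool (IT, PT, IT+PT), sequence (T2W,
#' ADC; optionally "both" = T2W+ADC), classification setting (L-vs-H,
#' L-vs-I+H) and cohort (D1 cross-validation, D2 hold-out): features are
#' selected on D1 only, the QDA model is cross-validated on D1
#' (patient-grouped) and refit on all of D1 for the D2 hold-out AUC. The
#' default grid has 3 x 2 x 2 x 2 = 24 AUC cells.
#'
#' @param table_d1,table_d2 feature tables of the two cohorts
#' @param settings classification settings to run
#' @param pools feature pools to run
#' @param sequences sequence sets to run ("T2W", "ADC", "both")
#' @param cv_runs,cv_folds cross-validation scheme on D1
#' @param p_threshold,k selection parameters
#' @param seed RNG seed (fold draws)
#' @param shrinkage QDA shrinkage
#' @return data.frame with one row per (pool, sequence, setting, cohort)
#'   and columns `auc`, `n`, `n_features`; failed cells (e.g. empty
#'   selection) carry `NA` with the reason in `note`
#' @export
experiment_report <- function(table_d1, table_d2,
                              settings = c("L_vs_H", "L_vs_IH"),
                              pools = c("IT", "PT", "IT_PT"),
                              sequences = c("T2W", "ADC"),
                              cv_runs = 100, cv_folds = 3,
                              p_threshold = 0.01, k = 10, seed = 1,
                              shrinkage = 1e-3) {
  rows <- list()
  for (pool in pools) for (sq in sequences) for (setting in settings) {
    cols <- pool_columns(table_d1, pool, sq)
    lab1 <- setting_labels(table_d1$risk, setting)
    lab2 <- setting_labels(table_d2$risk, setting)
    d1 <- table_d1[lab1$keep, , drop = FALSE]
    d2 <- table_d2[lab2$keep, , drop = FALSE]
    note <- ""
    sel <- tryCatch(
      select_features(d1[, c("risk", cols)], risk = d1$risk,
                      setting = setting, p_threshold = p_threshold, k = k),
      radpt_empty_selection = function(e) "empty selection",
      radpt_input_error = function(e) "single-class cohort")
    if (is.character(sel) || is.null(sel)) {
      auc_cv <- NA_real_; auc_d2 <- NA_real_; nf <- 0L
      note <- if (is.character(sel)) sel else "empty selection"
      sel <- NULL
    } else {
      nf <- nrow(sel)
      cv <- cross_validate(d1, lab1$y, d1$patient_id, sel$feature,
                           runs = cv_runs, folds = cv_folds, seed = seed,
                           shrinkage = shrinkage)
      auc_cv <- attr(cv, "mean_auc")
      ho <- fit_and_holdout(d1, d2, lab1$y, lab2$y, sel$feature, shrinkage)
      auc_d2 <- ho$auc_d2
    }
    rows[[length(rows) + 1]] <- data.frame(
      pool = pool, sequence = sq, setting = setting,
      cohort = c("D1_CV", "D2_holdout"),
      auc = c(auc_cv, auc_d2),
      n = c(nrow(d1), nrow(d2)), n_features = nf, note = note,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
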