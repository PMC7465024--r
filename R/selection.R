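#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of all group assignments when `n0 + n1 <= 12`
#' (two-sided p = probability, under random assignment of the observed
#' values, of a U statistic at least as far from its mean as observed;
#' ties handled by permutation of the observed values). Larger samples use
#' the normal approximation with tie correction and continuity correction.
#' All-tied data returns p = 1.
#'
#' @param x,y numeric vectors (both nonempty)
#' @return list with `U` (statistic of group `x`) and `p.value`
#' @export
ranksum_test <- function(x, y) {
  if (!length(x) || !length(y))
    stop_radpt("radpt_input_error", "both groups must be nonempty")
  n0 <- length(x); n1 <- length(y)
  all <- c(x, y)
  r <- rank(all)
  U <- sum(r[seq_len(n0)]) - n0 * (n0 + 1) / 2
  mu <- n0 * n1 / 2
  if (max(all) == min(all)) return(list(U = U, p.value = 1))
  if (n0 + n1 <= 12) {
    idx <- combn(n0 + n1, n0)
    us <- apply(idx, 2, function(ii)
      sum(r[ii]) - n0 * (n0 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p.value = p))
  }
  N <- n0 + n1
  ties <- table(all)
  tiecorr <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n0 * n1 / 12 * ((N + 1) - tiecorr)
  if (sigma2 <= 0) return(list(U = U, p.value = 1))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  list(U = U, p.value = min(1, 2 * pnorm(-abs(z))))
}

#' Plug-in mutual information (nats)
#'
#' Continuous arguments are discretized into `n_bins` equal-frequency bins
#' (quantile breaks; duplicated breaks collapsed); discrete arguments
#' (factors, or vectors with at most `n_bins` distinct values) are used
#' as-is. A constant argument gives MI = 0.
#'
#' @param x,y vectors of equal length
#' @param n_bins bins for continuous arguments
#' @return mutual information in nats (`>= 0`)
#' @export
mutual_information <- function(x, y, n_bins = 10) {
  disc <- function(v) {
    if (is.factor(v) || is.character(v)) return(as.integer(factor(v)))
    u <- unique(v)
    if (length(u) <= n_bins) return(as.integer(factor(v)))
    br <- unique(quantile(v, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2) return(rep(1L, length(v)))
    as.integer(cut(v, br, include.lowest = TRUE))
  }
  a <- disc(x); b <- disc(y)
  if (length(unique(a)) < 2 || length(unique(b)) < 2) return(0)
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pa, pb)[nz]))
  max(0, mi)
}

#' Greedy minimum-redundancy-maximum-relevance feature ranking (MID scheme)
#'
#' The first feature maximizes relevance I(f; y); each subsequent pick
#' maximizes relevance minus the mean mutual information with the already
#' selected features. Ties are broken deterministically by feature name.
#'
#' @param table data.frame of candidate feature columns
#' @param labels class labels (factor or vector)
#' @param k number of features to rank
#' @param n_bins discretization for [mutual_information()]
#' @return data.frame with `feature`, `mrmr_score`, `rank`
#' @export
mrmr_rank <- function(table, labels, k = 10, n_bins = 10) {
  feats <- names(table)
  if (length(feats) < k) {
    warning(sprintf("only %d candidate features; returning all",
                    length(feats)))
    k <- length(feats)
  }
  relevance <- vapply(feats, function(f)
    mutual_information(table[[f]], labels, n_bins), numeric(1))
  selected <- character(0)
  scores <- numeric(0)
  # cache pairwise MI with already-selected features
  redund <- matrix(0, nrow = length(feats), ncol = 0,
                   dimnames = list(feats, NULL))
  for (step in seq_len(k)) {
    remaining <- setdiff(feats, selected)
    crit <- if (!length(selected)) relevance[remaining]
            else relevance[remaining] -
              rowMeans(redund[remaining, , drop = FALSE])
    ord <- order(-crit, remaining)  # deterministic name tie-break
    pick <- remaining[ord[1]]
    selected <- c(selected, pick)
    scores <- c(scores, crit[pick])
    if (step < k) {
      mi_new <- vapply(feats, function(f)
        if (f == pick) 0 else
          mutual_information(table[[f]], table[[pick]], n_bins),
        numeric(1))
      redund <- cbind(redund, mi_new)
    }
  }
  data.frame(feature = selected, mrmr_score = unname(scores),
             rank = seq_along(selected), stringsAsFactors = FALSE)
}

#' Binary labels for a classification setting
#'
#' `L_vs_H` drops intermediate lesions; `L_vs_IH` merges intermediate and
#' high as positives. Positives are the higher-risk group.
#'
#' @param risk vector of "L"/"I"/"H"
#' @param setting "L_vs_H" or "L_vs_IH"
#' @return list with `keep` (logical row filter) and `y` (0/1 labels for
#'   the kept rows; 1 = positive)
#' @export
setting_labels <- function(risk, setting = c("L_vs_H", "L_vs_IH")) {
  setting <- match.arg(setting)
  if (setting == "L_vs_H") {
    keep <- risk %in% c("L", "H")
    y <- as.integer(risk[keep] == "H")
  } else {
    keep <- rep(TRUE, length(risk))
    y <- as.integer(risk %in% c("I", "H"))
  }
  list(keep = keep, y = y)
}

#' Wilcoxon prefilter followed by MRMR ranking of the top-k features
#'
#' Features whose two-sided rank-sum p-value (positive vs negative group)
#' is below `p_threshold` survive the prefilter ("unadjusted" p-values, no
#' multiplicity correction); the survivors are rank-ordered by greedy MRMR.
#' Feature columns with missing values are compared pair-wise complete.
#'
#' @param table feature table (see [extract_all()])
#' @param risk risk labels aligned with the rows (defaults to
#'   `table$risk`)
#' @param setting classification setting, see [setting_labels()]
#' @param p_threshold prefilter threshold on the unadjusted p-value
#' @param k number of features to rank
#' @return a `selection_result`: data.frame with `feature`, `p_value`,
#'   `mrmr_score`, `rank`, plus attributes `setting` and `pool`
#' @export
select_features <- function(table, risk = NULL,
                            setting = c("L_vs_H", "L_vs_IH"),
                            p_threshold = 0.01, k = 10) {
  setting <- match.arg(setting)
  risk <- risk %||% table$risk
  lab <- setting_labels(risk, setting)
  fcols <- feature_cols(table)
  sub <- table[lab$keep, fcols, drop = FALSE]
  y <- lab$y
  if (length(unique(y)) < 2)
    stop_radpt("radpt_input_error", "need both classes for selection")
  pvals <- vapply(fcols, function(f) {
    v <- sub[[f]]
    ok <- is.finite(v)
    if (length(unique(y[ok])) < 2) return(1)
    ranksum_test(v[ok & y == 1], v[ok & y == 0])$p.value
  }, numeric(1))
  surv <- fcols[pvals < p_threshold]
  if (!length(surv))
    stop_radpt("radpt_empty_selection",
               "no feature passed the p < %g prefilter", p_threshold)
  ranked <- mrmr_rank(sub[, surv, drop = FALSE], y, k = min(k, length(surv)))
  out <- data.frame(feature = ranked$feature,
                    p_value = unname(pvals[ranked$feature]),
                    mrmr_score = ranked$mrmr_score,
                    rank = ranked$rank, stringsAsFactors = FALSE)
  attr(out, "setting") <- setting
  attr(out, "n_survivors") <- length(surv)
  class(out) <- c("selection_result", "data.frame")
  out
}
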