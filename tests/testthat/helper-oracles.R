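# Independent (naive, loop-based) oracles for the image operators, plus
# shared fixtures. These deliberately re-derive every definition from
# scratch rather than calling the package's optimized paths.

reflect_idx1 <- function(i, n) {
  # symmetric (half-sample) reflection, 1-based
  i0 <- i - 1
  if (i0 < 0) i0 <- -i0 - 1
  if (i0 >= n) i0 <- 2 * n - i0 - 1
  i0 + 1
}

naive_conv2_reflect <- function(img, ker) {
  nr <- nrow(img); nc <- ncol(img)
  kr <- nrow(ker); kc <- ncol(ker)
  ci <- kr %/% 2; cj <- kc %/% 2
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    acc <- 0
    for (a in 1:kr) for (b in 1:kc) {
      ii <- reflect_idx1(i + a - 1 - ci, nr)
      jj <- reflect_idx1(j + b - 1 - cj, nc)
      acc <- acc + ker[a, b] * img[ii, jj]
    }
    out[i, j] <- acc
  }
  out
}

brute_edt <- function(mask, sx, sy) {
  src <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  for (i in 1:nrow(mask)) for (j in 1:ncol(mask)) {
    d2 <- ((i - src[, 1]) * sx)^2 + ((j - src[, 2]) * sy)^2
    out[i, j] <- sqrt(min(d2))
  }
  out
}

naive_window_stats <- function(img, w, i, j) {
  h <- w %/% 2
  ii <- max(1, i - h):min(nrow(img), i + h)
  jj <- max(1, j - h):min(ncol(img), j + h)
  v <- as.vector(img[ii, jj])
  list(mean = mean(v), median = median(v),
       sd = if (length(v) > 1) sd(v) else 0,
       range = max(v) - min(v))
}

# literal transcription of the 13 co-occurrence statistics with explicit
# loops (natural log, 0*log0 = 0); independent of haralick_stats()
literal_haralick <- function(P) {
  L <- nrow(P)
  lg <- function(x) if (x > 0) log(x) else 0
  px <- rowSums(P); py <- colSums(P)
  energy <- 0; entropy <- 0; contrast <- 0; idm <- 0; sij <- 0
  for (i in 1:L) for (j in 1:L) {
    p <- P[i, j]
    energy <- energy + p^2
    if (p > 0) entropy <- entropy - p * lg(p)
    contrast <- contrast + (i - j)^2 * p
    idm <- idm + p / (1 + (i - j)^2)
    sij <- sij + (i - 1) * (j - 1) * p
  }
  mux <- sum((0:(L - 1)) * px); muy <- sum((0:(L - 1)) * py)
  vx <- sum(((0:(L - 1)) - mux)^2 * px)
  vy <- sum(((0:(L - 1)) - muy)^2 * py)
  corr <- if (sqrt(vx * vy) > 1e-12) (sij - mux * muy) / sqrt(vx * vy) else 0
  ps <- numeric(2 * L - 1)
  pd <- numeric(L)
  for (i in 1:L) for (j in 1:L) {
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
  }
  sa <- sum((0:(2 * L - 2)) * ps)
  sv <- sum(((0:(2 * L - 2)) - sa)^2 * ps)
  se <- -sum(sapply(ps, function(p) if (p > 0) p * log(p) else 0))
  mud <- sum((0:(L - 1)) * pd)
  dv <- sum(((0:(L - 1)) - mud)^2 * pd)
  de <- -sum(sapply(pd, function(p) if (p > 0) p * log(p) else 0))
  hx <- -sum(sapply(px, function(p) if (p > 0) p * log(p) else 0))
  hy <- -sum(sapply(py, function(p) if (p > 0) p * log(p) else 0))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:L) for (j in 1:L) {
    q <- px[i] * py[j]
    if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * lg(q)
    if (q > 0) hxy2 <- hxy2 - q * lg(q)
  }
  imc1 <- if (max(hx, hy) > 1e-12) (entropy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(energy = energy, entropy = entropy, contrast = contrast,
    correlation = corr, variance = vx, idm = idm, sum_average = sa,
    sum_variance = sv, sum_entropy = se, diff_variance = dv,
    diff_entropy = de, imc1 = imc1, imc2 = imc2)
}

# naive per-pixel windowed Haralick value: window clipped at borders,
# intersected with the ROI, min-max quantized, symmetric GLCM over the four
# distance-1 offsets
naive_haralick_pixel <- function(img, roi, i, j, w, n_levels) {
  h <- w %/% 2
  ii <- max(1, i - h):min(nrow(img), i + h)
  jj <- max(1, j - h):min(ncol(img), j + h)
  win <- img[ii, jj, drop = FALSE]
  wroi <- roi[ii, jj, drop = FALSE]
  if (!any(wroi)) return(rep(NA_real_, 13))
  v <- win[wroi]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(win), ncol(win))
  if (hi > lo) {
    lev <- pmin(floor((win[wroi] - lo) / (hi - lo) * n_levels), n_levels - 1)
    q[wroi] <- as.integer(lev)
  } else q[wroi] <- 0L
  P <- tryCatch(glcm(q, n_levels = n_levels),
                radpt_empty_pairs = function(e) NULL)
  if (is.null(P)) return(rep(NA_real_, 13))
  literal_haralick(P)
}

# small cached fixtures -----------------------------------------------------

.fixture_env <- new.env()

fixture_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- phantom_config(n_patients = 2, seed = 42,
                          n_slices_range = c(3, 4),
                          class_mix = c(L = 0.5, I = 0, H = 0.5))
    .fixture_env$study <- preprocess_study(generate_study(cfg, 1))
  }
  .fixture_env$study
}

fixture_features <- function() {
  if (is.null(.fixture_env$features))
    .fixture_env$features <- extract_all(fixture_study())
  .fixture_env$features
}

# small labelled table for selection/classifier tests: two informative
# features among noise, grouped patients
fixture_labelled_table <- function(n_patients = 30, seed = 5) {
  set.seed(seed)
  n <- n_patients
  risk <- sample(c("L", "H"), n, replace = TRUE)
  y <- as.integer(risk == "H")
  tab <- data.frame(patient_id = sprintf("P%02d", 1:n),
                    lesion_id = sprintf("P%02d_L1", 1:n),
                    risk = risk, pirads = ifelse(y == 1, 4, 2),
                    stringsAsFactors = FALSE)
  tab[["T2W.IT.fo.mean3.mean"]] <- y * 2 + rnorm(n, sd = 0.7)
  tab[["ADC.IT.signal.raw.mean"]] <- -y * 1.5 + rnorm(n, sd = 0.7)
  for (k in 1:8)
    tab[[sprintf("T2W.PT_3_6.gabor.l3o%02d.mean", k)]] <- rnorm(n)
  attr(tab, "meta_cols") <- c("patient_id", "lesion_id", "risk", "pirads")
  tab
}
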