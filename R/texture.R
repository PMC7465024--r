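#' Min-max quantization of an image within a ROI
#'
#' Equal-width binning of the within-ROI intensity range into `n_levels`
#' levels `0..n_levels-1`; a constant ROI maps to level 0. Pixels outside
#' the ROI are `NA`.
#'
#' @param image matrix
#' @param roi_mask logical matrix
#' @param n_levels number of gray levels (>= 2)
#' @return integer matrix with levels inside the ROI, `NA` outside
#' @export
quantize_image <- function(image, roi_mask, n_levels = 64) {
  stopifnot(n_levels >= 2)
  if (!any(roi_mask)) stop_radpt("radpt_input_error", "empty ROI")
  v <- image[roi_mask]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi - lo <= 0) {
    q[roi_mask] <- 0L
  } else {
    lev <- floor((image[roi_mask] - lo) / (hi - lo) * n_levels)
    q[roi_mask] <- as.integer(pmin(lev, n_levels - 1))
  }
  q
}

# the four distance-1 GLCM offsets (row, col)
glcm_offsets <- function() rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))

#' Gray-level co-occurrence matrix of a quantized window
#'
#' Pair counts of levels at the given pixel offsets, accumulated over the
#' window; `NA` entries (outside-ROI pixels) never pair. With
#' `symmetric = TRUE` each pair is counted in both orders. Entries are
#' normalized to sum to 1.
#'
#' @param quantized integer matrix of levels `0..n_levels-1` (NA allowed)
#' @param offsets integer matrix with one (row, col) offset per row;
#'   default: the four distance-1 directions
#' @param symmetric count each pair in both orders
#' @param n_levels matrix size; defaults to `max(level) + 1`
#' @return `n_levels` x `n_levels` matrix summing to 1
#' @export
glcm <- function(quantized, offsets = glcm_offsets(), symmetric = TRUE,
                 n_levels = NULL) {
  if (is.null(n_levels)) n_levels <- max(quantized, na.rm = TRUE) + 1L
  if (nrow(offsets) < 1) stop_radpt("radpt_input_error", "no offsets")
  nr <- nrow(quantized); nc <- ncol(quantized)
  counts <- matrix(0, n_levels, n_levels)
  for (o in seq_len(nrow(offsets))) {
    di <- offsets[o, 1]; dj <- offsets[o, 2]
    for (i in seq_len(nr)) {
      ii <- i + di
      if (ii < 1 || ii > nr) next
      for (j in seq_len(nc)) {
        jj <- j + dj
        if (jj < 1 || jj > nc) next
        a <- quantized[i, j]; b <- quantized[ii, jj]
        if (is.na(a) || is.na(b)) next
        counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  tot <- sum(counts)
  if (tot == 0)
    stop_radpt("radpt_empty_pairs", "no co-occurring pairs in window")
  counts / tot
}

#' The 13 Haralick statistics of a normalized GLCM
#'
#' Energy, entropy, contrast, correlation, variance (sum of squares),
#' inverse difference moment, sum average, sum variance, sum entropy,
#' difference variance, difference entropy, and the two information
#' measures of correlation. Entropies use the natural log with
#' `0 * log 0 := 0`; sum variance is centred on the sum average;
#' correlation of a zero-variance marginal is 0 by convention.
#'
#' @param P normalized co-occurrence matrix (entries sum to 1)
#' @return named numeric vector of length 13
#' @export
haralick_stats <- function(P) {
  L <- nrow(P)
  i <- matrix(rep(0:(L - 1), L), L, L)       # row level
  j <- t(i)                                  # col level
  nz <- P > 0
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  px <- rowSums(P); py <- colSums(P)
  energy <- sum(P^2)
  entropy <- -sum(xlogx(P))
  contrast <- sum((i - j)^2 * P)
  mux <- sum((0:(L - 1)) * px); muy <- sum((0:(L - 1)) * py)
  vx <- sum(((0:(L - 1)) - mux)^2 * px)
  vy <- sum(((0:(L - 1)) - muy)^2 * py)
  sdxy <- sqrt(vx * vy)
  correlation <- if (sdxy > 1e-12) (sum(i * j * P) - mux * muy) / sdxy else 0
  idm <- sum(P / (1 + (i - j)^2))
  ks <- 0:(2 * L - 2)
  ps <- vapply(ks, function(k) sum(P[i + j == k]), numeric(1))
  sum_average <- sum(ks * ps)
  sum_variance <- sum((ks - sum_average)^2 * ps)
  sum_entropy <- -sum(xlogx(ps))
  kd <- 0:(L - 1)
  pd <- vapply(kd, function(k) sum(P[abs(i - j) == k]), numeric(1))
  mud <- sum(kd * pd)
  diff_variance <- sum((kd - mud)^2 * pd)
  diff_entropy <- -sum(xlogx(pd))
  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(P[nz] * log(pxpy[nz]))
  hxy2 <- -sum(xlogx(pxpy))
  denom <- max(hx, hy)
  imc1 <- if (denom > 1e-12) (entropy - hxy1) / denom else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(energy = energy, entropy = entropy, contrast = contrast,
    correlation = correlation, variance = vx, idm = idm,
    sum_average = sum_average, sum_variance = sum_variance,
    sum_entropy = sum_entropy, diff_variance = diff_variance,
    diff_entropy = diff_entropy, imc1 = imc1, imc2 = imc2)
}

haralick_stat_names <- function()
  c("energy", "entropy", "contrast", "correlation", "variance", "idm",
    "sum_average", "sum_variance", "sum_entropy", "diff_variance",
    "diff_entropy", "imc1", "imc2")

#' Windowed Haralick feature maps
#'
#' For every ROI pixel, the centred window (clipped at image borders and
#' intersected with the ROI) is min-max quantized to `n_levels` levels and
#' the symmetric GLCM over the four distance-1 directions is summarized by
#' the 13 Haralick statistics. With the default 3 window sizes this yields
#' 39 maps.
#'
#' @param image matrix
#' @param mask logical ROI matrix
#' @param window_sizes odd window sizes in pixels
#' @param n_levels quantization depth
#' @return 3D array (rows, cols, `13 * length(window_sizes)`), `NA` outside
#'   the ROI; the third dimension is named `w{size}_{stat}`
#' @export
haralick_maps <- function(image, mask, window_sizes = c(3, 5, 7),
                          n_levels = 64) {
  if (any(window_sizes %% 2 == 0))
    stop_radpt("radpt_input_error", "window sizes must be odd")
  out <- .haralick_maps_cpp(image, matrix(as.integer(mask), nrow(mask)),
                            as.integer(window_sizes), as.integer(n_levels))
  dimnames(out) <- list(NULL, NULL,
    as.vector(t(outer(paste0("w", window_sizes), haralick_stat_names(),
                      paste, sep = "_"))))
  out
}

#' Gabor filter bank
#'
#' Real-part Gabor kernels (oriented cosine under an isotropic Gaussian
#' envelope, sigma = 0.56 * wavelength, support 2.5 sigma), DC-subtracted
#' to zero mean and scaled to unit L2 norm. The default bank is 4
#' wavelengths x 19 orientations evenly spaced on `[0, pi)` = 76 kernels.
#'
#' @param wavelengths wavelengths in pixels
#' @param n_orientations number of evenly spaced orientations on `[0, pi)`
#' @param allow_any_bank permit bank sizes other than 76
#' @return named list of kernels (`l{lambda}o{index}`), with attributes
#'   `wavelength` and `theta` on each kernel
#' @export
gabor_bank <- function(wavelengths = c(3, 4, 5, 6), n_orientations = 19,
                       allow_any_bank = FALSE) {
  nk <- length(wavelengths) * n_orientations
  if (nk != 76 && !allow_any_bank)
    stop_radpt("radpt_config_error",
               "default Gabor bank must have 76 kernels (got %d); set allow_any_bank = TRUE to override",
               nk)
  bank <- list()
  for (lam in wavelengths) {
    sigma <- 0.56 * lam
    h <- ceiling(2.5 * sigma)
    x <- matrix(rep(-h:h, 2 * h + 1), 2 * h + 1)
    y <- t(x)
    for (oi in seq_len(n_orientations) - 1) {
      theta <- oi * pi / n_orientations
      xr <- x * cos(theta) + y * sin(theta)
      yr <- -x * sin(theta) + y * cos(theta)
      k <- exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lam)
      k <- k - mean(k)
      k <- k / sqrt(sum(k^2))
      attr(k, "wavelength") <- lam
      attr(k, "theta") <- theta
      bank[[sprintf("l%go%02d", lam, oi)]] <- k
    }
  }
  bank
}

#' Gabor response maps
#'
#' Same-size filter responses (cross-correlation, symmetric border
#' reflection) for every kernel of the bank.
#'
#' @param image matrix
#' @param bank a [gabor_bank()]
#' @return 3D array (rows, cols, kernels) named like the bank
#' @export
gabor_maps <- function(image, bank = gabor_bank()) {
  conv_bank_fft(image, bank)
}

#' The 25 Laws texture energy kernels
#'
#' Outer products of the level, edge, spot, wave and ripple vectors
#' L5 = (1,4,6,4,1), E5 = (-1,-2,0,2,1), S5 = (-1,0,2,0,-1),
#' W5 = (-1,2,0,-2,1), R5 = (1,-4,6,-4,1); the first factor varies along
#' rows. All kernels with at least one zero-sum factor are themselves
#' zero-sum.
#'
#' @return named list of 25 5x5 kernels (`L5E5`, ...)
#' @export
laws_kernels <- function() {
  v <- list(L5 = c(1, 4, 6, 4, 1), E5 = c(-1, -2, 0, 2, 1),
            S5 = c(-1, 0, 2, 0, -1), W5 = c(-1, 2, 0, -2, 1),
            R5 = c(1, -4, 6, -4, 1))
  out <- list()
  for (a in names(v))
    for (b in names(v))
      out[[paste0(a, b)]] <- outer(v[[a]], v[[b]])
  out
}

#' Laws texture energy maps
#'
#' @param image matrix (at least 5x5)
#' @return 3D array (rows, cols, 25), symmetric border reflection
#' @export
laws_maps <- function(image) {
  if (nrow(image) < 5 || ncol(image) < 5)
    stop_radpt("radpt_input_error", "image must be at least 5x5")
  conv_bank_fft(image, laws_kernels())
}

sobel_kernels <- function() {
  list(x = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3),  # d/d(row)
       y = t(matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)))
}

#' First-order statistic maps and the raw signal feature
#'
#' The nine maps: 3x3 window mean, median, standard deviation (n-1
#' denominator) and range; Sobel row-gradient, column-gradient and
#' gradient magnitude; 5x5 window mean and median. Windows are clipped at
#' the image border. The signal feature is the raw within-ROI mean
#' intensity.
#'
#' @param image matrix
#' @param mask logical ROI matrix
#' @return list with `maps` (3D array, 9 named planes) and `signal`
#' @export
first_order_maps <- function(image, mask) {
  if (!any(mask)) stop_radpt("radpt_input_error", "empty ROI")
  w3 <- .window_stats_cpp(image, 3L)
  w5 <- .window_stats_cpp(image, 5L)
  sk <- sobel_kernels()
  gx <- .conv2_reflect_cpp(image, sk$x)
  gy <- .conv2_reflect_cpp(image, sk$y)
  nm <- c("mean3", "median3", "sd3", "range3", "sobelx", "sobely",
          "sobelmag", "mean5", "median5")
  maps <- array(0, dim = c(nrow(image), ncol(image), 9),
                dimnames = list(NULL, NULL, nm))
  maps[, , "mean3"] <- w3$mean
  maps[, , "median3"] <- w3$median
  maps[, , "sd3"] <- w3$sd
  maps[, , "range3"] <- w3$range
  maps[, , "sobelx"] <- gx
  maps[, , "sobely"] <- gy
  maps[, , "sobelmag"] <- sqrt(gx^2 + gy^2)
  maps[, , "mean5"] <- w5$mean
  maps[, , "median5"] <- w5$median
  list(maps = maps, signal = mean(image[mask]))
}

#' CoLlAGe feature maps (optional extension set)
#'
#' Per pixel, the dominant local gradient orientation (first principal
#' direction of the stacked Sobel gradient vectors over the window, from
#' the 2x2 structure tensor) is quantized to `n_angle_bins` equal-width
#' bins over `[0, pi)`; the co-occurrence of quantized orientations within
#' the window-and-ROI is summarized by the 13 Haralick statistics.
#' Zero-gradient windows take orientation bin 0 by convention.
#'
#' @param image matrix
#' @param mask logical ROI matrix
#' @param window odd window size (default 5)
#' @param n_angle_bins orientation bins (default 64)
#' @return 3D array (rows, cols, 13), `NA` outside the ROI
#' @export
collage_maps <- function(image, mask, window = 5, n_angle_bins = 64) {
  if (window %% 2 == 0 || window < 3)
    stop_radpt("radpt_input_error", "window must be odd and >= 3")
  out <- .collage_maps_cpp(image, matrix(as.integer(mask), nrow(mask)),
                           as.integer(window), as.integer(n_angle_bins))
  dimnames(out) <- list(NULL, NULL,
                        paste0("w", window, "_", haralick_stat_names()))
  out
}

#' Dominant gradient orientation map (CoLlAGe first stage)
#'
#' @param image matrix
#' @param window odd window size
#' @return matrix of orientations in `[0, pi)`
#' @export
collage_orientation <- function(image, window = 5) {
  .collage_orientation_cpp(image, as.integer(window))
}

#' Aggregate a feature map over a ROI
#'
#' @param map matrix (or vector of pooled map values)
#' @param roi_mask logical matrix; ignored when `map` is a plain vector
#' @param aggregator "mean", "sd", "skewness" or "kurtosis" (standardized
#'   3rd/4th central moments; kurtosis is not excess)
#' @return scalar; `NA` when the ROI is empty or all map values are missing
#' @export
aggregate_map <- function(map, roi_mask = NULL,
                          aggregator = c("mean", "sd", "skewness",
                                         "kurtosis")) {
  aggregator <- match.arg(aggregator)
  v <- if (is.null(roi_mask)) map else map[roi_mask]
  v <- v[is.finite(v)]
  if (!length(v)) return(NA_real_)
  moment_stat(v, aggregator)
}
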