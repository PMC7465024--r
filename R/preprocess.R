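#' Preprocessing configuration
#'
#' @param target_pixel_spacing in-plane target pixel size in mm
#' @param target_slice_thickness through-plane target thickness in mm
#' @param crop_padding_mm padding around ROI bounding boxes in mm
#' @param standardization intensity standardization method:
#'   `"zscore_in_prostate"` (z-score using within-prostate mean/SD),
#'   `"histogram_landmarks"` (piecewise-linear alignment of within-prostate
#'   deciles to a fixed standard-normal template), or `"none"`. Both are
#'   documented stand-ins for published scanner-drift / bias-field
#'   corrections that this package does not re-derive.
#' @export
preprocess_config <- function(target_pixel_spacing = 0.5,
                              target_slice_thickness = 3,
                              crop_padding_mm = 2,
                              standardization = c("zscore_in_prostate",
                                                  "histogram_landmarks",
                                                  "none")) {
  standardization <- match.arg(standardization)
  stopifnot(target_pixel_spacing > 0, target_slice_thickness > 0,
            crop_padding_mm >= 0)
  structure(list(target_pixel_spacing = target_pixel_spacing,
                 target_slice_thickness = target_slice_thickness,
                 crop_padding_mm = crop_padding_mm,
                 standardization = standardization),
            class = "preprocess_config")
}

# bilinear sample of matrix `m` at fractional 0-based coordinates (u, v);
# coordinates are clamped to the grid
bilinear_sample <- function(m, u, v) {
  nr <- nrow(m); nc <- ncol(m)
  u <- pmin(pmax(u, 0), nr - 1)
  v <- pmin(pmax(v, 0), nc - 1)
  i0 <- pmin(floor(u), nr - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(v), nc - 2); j0 <- pmax(j0, 0)
  fu <- u - i0; fv <- v - j0
  idx <- function(i, j) m[cbind(i + 1, j + 1)]
  (1 - fu) * (1 - fv) * idx(i0, j0) +
    fu * (1 - fv) * idx(i0 + 1, j0) +
    (1 - fu) * fv * idx(i0, j0 + 1) +
    fu * fv * idx(i0 + 1, j0 + 1)
}

#' Resample a 2D grid (or each slice of a 3D grid) to a target pixel spacing
#'
#' Intensities are bilinearly interpolated; masks (`method = "nearest"`)
#' use nearest-neighbour with 0.5-ties rounding toward the lower index.
#' Pixel coordinates are 0-based with physical position = index x spacing.
#' The physical extent is preserved to within one pixel
#' (`n_out = round(n_in * spacing / target)`).
#'
#' @param image matrix or 3D array
#' @param spacing current in-plane spacing (mm, scalar or length-2)
#' @param target_spacing requested spacing in mm
#' @param method "bilinear" for images, "nearest" for masks
#' @return list with `image` and `spacing`
#' @export
resample_to_grid <- function(image, spacing, target_spacing,
                             method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (any(spacing <= 0) || target_spacing <= 0)
    stop_radpt("radpt_input_error", "spacings must be positive")
  spacing <- rep(spacing, length.out = 2)
  is3d <- length(dim(image)) == 3
  one <- function(m) {
    if (all(abs(spacing - target_spacing) < 1e-12)) return(m)
    nr <- max(2L, as.integer(round(nrow(m) * spacing[1] / target_spacing)))
    nc <- max(2L, as.integer(round(ncol(m) * spacing[2] / target_spacing)))
    u <- ((seq_len(nr) - 1) * target_spacing) / spacing[1]
    v <- ((seq_len(nc) - 1) * target_spacing) / spacing[2]
    if (method == "bilinear") {
      uu <- matrix(rep(u, nc), nr, nc)
      vv <- matrix(rep(v, each = nr), nr, nc)
      matrix(bilinear_sample(m, as.vector(uu), as.vector(vv)), nr, nc)
    } else {
      # ties at .5 round toward the lower index
      iu <- pmin(pmax(ceiling(u - 0.5), 0), nrow(m) - 1)
      iv <- pmin(pmax(ceiling(v - 0.5), 0), ncol(m) - 1)
      m[iu + 1, iv + 1, drop = FALSE]
    }
  }
  if (is3d) {
    sl <- lapply(seq_len(dim(image)[3]), function(z) one(image[, , z]))
    out <- array(unlist(sl), dim = c(dim(sl[[1]]), length(sl)))
    if (is.logical(image)) out <- array(as.logical(out), dim = dim(out))
  } else {
    out <- one(image)
    if (is.logical(image)) out <- matrix(as.logical(out), nrow(out))
  }
  list(image = out, spacing = c(target_spacing, target_spacing))
}

#' Interpolate a volume to a target slice thickness
#'
#' Linear interpolation along the slice axis (nearest-neighbour for logical
#' masks); in-plane grids are unchanged. Slice positions are 0-based,
#' physical position = slice index x thickness.
#'
#' @param volume 3D array
#' @param thickness current slice thickness (mm)
#' @param target_thickness requested thickness (mm)
#' @return list with `volume` and `thickness`
#' @export
interpolate_slices <- function(volume, thickness, target_thickness) {
  stopifnot(length(dim(volume)) == 3)
  if (thickness <= 0 || target_thickness <= 0)
    stop_radpt("radpt_input_error", "thicknesses must be positive")
  nz <- dim(volume)[3]
  if (nz < 2) {
    warning("single-slice volume returned unchanged")
    return(list(volume = volume, thickness = thickness))
  }
  if (abs(thickness - target_thickness) < 1e-12)
    return(list(volume = volume, thickness = thickness))
  nz_out <- max(2L, as.integer(round(nz * thickness / target_thickness)))
  w <- ((seq_len(nz_out) - 1) * target_thickness) / thickness
  w <- pmin(pmax(w, 0), nz - 1)
  out <- array(0, dim = c(dim(volume)[1:2], nz_out))
  for (k in seq_len(nz_out)) {
    if (is.logical(volume)) {
      z <- pmin(pmax(ceiling(w[k] - 0.5), 0), nz - 1)
      out[, , k] <- volume[, , z + 1]
    } else {
      z0 <- min(floor(w[k]), nz - 2)
      f <- w[k] - z0
      out[, , k] <- (1 - f) * volume[, , z0 + 1] + f * volume[, , z0 + 2]
    }
  }
  if (is.logical(volume)) out <- array(as.logical(out), dim = dim(out))
  list(volume = out, thickness = target_thickness)
}

#' Standardize image intensities within the prostate
#'
#' `zscore_in_prostate` maps the image so the within-prostate voxels have
#' mean 0 and SD 1 (applied to the whole grid). `histogram_landmarks`
#' piecewise-linearly maps within-prostate deciles onto the standard-normal
#' decile template `qnorm((1:9)/10)` with linear extension beyond the end
#' landmarks; the map is monotone in the input intensities.
#'
#' @param image matrix or 3D array
#' @param prostate_mask logical grid of the same shape
#' @param method "zscore_in_prostate", "histogram_landmarks" or "none"
#' @return standardized image of the same shape
#' @export
standardize_intensity <- function(image, prostate_mask,
                                  method = c("zscore_in_prostate",
                                             "histogram_landmarks",
                                             "none")) {
  method <- match.arg(method)
  if (method == "none") return(image)
  if (!any(prostate_mask))
    stop_radpt("radpt_input_error", "prostate mask is empty")
  v <- image[prostate_mask]
  if (method == "zscore_in_prostate") {
    s <- stats::sd(v)
    if (s < 1e-12)
      stop_radpt("radpt_degenerate_error",
                 "zero within-prostate variance")
    return((image - mean(v)) / s)
  }
  land <- unname(quantile(v, probs = (1:9) / 10, type = 7))
  if (land[9] - land[1] < 1e-12)
    stop_radpt("radpt_degenerate_error", "zero within-prostate variance")
  tmpl <- qnorm((1:9) / 10)
  # collapse duplicated landmarks (heavy ties) keeping monotonicity
  keep <- c(TRUE, diff(land) > 1e-12)
  land <- land[keep]; tmpl <- tmpl[keep]
  x <- as.vector(image)
  y <- stats::approx(land, tmpl, xout = x, rule = 2)$y
  # linear extension beyond the outer landmarks
  k <- length(land)
  slope_lo <- (tmpl[2] - tmpl[1]) / (land[2] - land[1])
  slope_hi <- (tmpl[k] - tmpl[k - 1]) / (land[k] - land[k - 1])
  lo <- x < land[1]; hi <- x > land[k]
  y[lo] <- tmpl[1] + (x[lo] - land[1]) * slope_lo
  y[hi] <- tmpl[k] + (x[hi] - land[k]) * slope_hi
  array(y, dim = dim(image) %||% length(x))
}

#' Crop a grid to the bounding box of a mask with physical padding
#'
#' The in-plane bounding box of the mask union is dilated by
#' `ceiling(padding_mm / spacing)` pixels on each side, clipped to the grid.
#' The returned 0-based `offset` allows exact coordinate round-trips
#' (pixel (i, j) of the crop is pixel (i + offset[1], j + offset[2]) of the
#' original, 0-based).
#'
#' @param image matrix or 3D array
#' @param roi_mask logical grid (same in-plane shape)
#' @param padding_mm physical padding in mm
#' @param spacing in-plane spacing in mm (scalar or length-2)
#' @return list with `image` (cropped) and `offset` (integer, 0-based)
#' @export
crop_to_roi <- function(image, roi_mask, padding_mm, spacing) {
  if (!any(roi_mask))
    stop_radpt("radpt_input_error", "empty ROI mask")
  spacing <- rep(spacing, length.out = 2)
  if (length(dim(roi_mask)) == 3)
    flat <- apply(roi_mask, c(1, 2), any)
  else flat <- roi_mask
  pad <- ceiling(padding_mm / spacing)
  rr <- range(which(apply(flat, 1, any)))
  cc <- range(which(apply(flat, 2, any)))
  r0 <- max(1, rr[1] - pad[1]); r1 <- min(nrow(flat), rr[2] + pad[1])
  c0 <- max(1, cc[1] - pad[2]); c1 <- min(ncol(flat), cc[2] + pad[2])
  out <- if (length(dim(image)) == 3) image[r0:r1, c0:c1, , drop = FALSE]
         else image[r0:r1, c0:c1, drop = FALSE]
  list(image = out, offset = as.integer(c(r0 - 1, c0 - 1)))
}

#' Paste a cropped region back into a grid (inverse of [crop_to_roi()])
#'
#' @param target grid to paste into
#' @param cropped cropped grid
#' @param offset 0-based offset as returned by [crop_to_roi()]
#' @export
paste_from_crop <- function(target, cropped, offset) {
  r <- seq_len(dim(cropped)[1]) + offset[1]
  c <- seq_len(dim(cropped)[2]) + offset[2]
  if (length(dim(target)) == 3) target[r, c, ] <- cropped
  else target[r, c] <- cropped
  target
}

#' Preprocess a phantom/clinical study
#'
#' Resamples both channels and all masks to the target in-plane spacing,
#' interpolates slices to the target thickness, and standardizes both
#' channels within the prostate. The same treatment is applied to T2W and
#' ADC.
#'
#' @param study a `radpt_study`
#' @param config a [preprocess_config()]
#' @return the preprocessed study
#' @export
preprocess_study <- function(study, config = preprocess_config()) {
  sp <- study$spacing
  tgt <- config$target_pixel_spacing
  res <- function(x, method) resample_to_grid(x, sp, tgt, method)$image
  study$t2w <- res(study$t2w, "bilinear")
  study$adc <- res(study$adc, "bilinear")
  study$prostate_mask <- res(study$prostate_mask, "nearest")
  study$lesions <- lapply(study$lesions, function(l) {
    l$mask <- res(l$mask, "nearest")
    l
  })
  study$spacing <- c(tgt, tgt)
  if (abs(study$slice_thickness - config$target_slice_thickness) > 1e-12) {
    th <- study$slice_thickness
    study$t2w <- interpolate_slices(study$t2w, th,
                                    config$target_slice_thickness)$volume
    study$adc <- interpolate_slices(study$adc, th,
                                    config$target_slice_thickness)$volume
    study$prostate_mask <- interpolate_slices(
      study$prostate_mask, th, config$target_slice_thickness)$volume
    study$lesions <- lapply(study$lesions, function(l) {
      l$mask <- interpolate_slices(l$mask, th,
                                   config$target_slice_thickness)$volume
      l
    })
    study$slice_thickness <- config$target_slice_thickness
  }
  if (config$standardization != "none") {
    method <- config$standardization
    study$t2w <- standardize_intensity(study$t2w, study$prostate_mask,
                                       method)
    study$adc <- standardize_intensity(study$adc, study$prostate_mask,
                                       method)
  }
  study
}
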