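#' Configuration for the synthetic bi-parametric MRI phantom cohort
#'
#' The phantom emulates the statistical structure the downstream analysis
#' relies on: two co-registered channels (a T2-weighted-like image in
#' arbitrary units and an ADC-like map in 10^-3 mm^2/s units), an elliptical
#' prostate, blob-shaped lesions, and class-dependent texture expressed as
#' Gaussian random fields whose variance and correlation length differ by
#' D'Amico risk class inside the lesion (`it_effect`) and, with separately
#' controllable strength, in the 3 mm peri-tumoral bands (`pt_effect`).
#' ADC inside the lesion is shifted downward with risk class (`adc_shift`,
#' in units of the ADC noise SD), mimicking lesion hypo-intensity on ADC.
#'
#' @param image_size in-plane grid size in pixels (square grid)
#' @param pixel_spacing in-plane pixel size in mm
#' @param slice_thickness through-plane slice thickness in mm
#' @param n_slices_range integer range (min, max) of slices per study
#' @param n_patients number of patients in a cohort
#' @param lesions_per_patient named probabilities over lesion counts
#'   (names "1", "2")
#' @param class_mix named probabilities over risk classes L, I, H; must sum
#'   to 1
#' @param it_effect per-class dimensionless intra-tumoral texture effect
#'   size (amplitude of the class-specific random field, in units of the
#'   channel noise SD)
#' @param it_sequences which channels carry the intra-tumoral texture
#'   effect, subset of `c("T2W", "ADC")`
#' @param pt_effect 3 x 4 matrix (classes L, I, H by 3 mm bands 0-3, 3-6,
#'   6-9, 9-12 mm) of dimensionless peri-tumoral effect sizes
#' @param pt_sequences channels carrying the peri-tumoral effect
#' @param adc_shift per-class additive shift of the lesion ADC mean in
#'   units of the ADC noise SD (negative = hypo-intense)
#' @param noise_sd list with elements `t2w` and `adc`: image noise SD per
#'   channel, in channel units
#' @param correlation_length_mm list with elements `background` (scalar),
#'   `lesion` and `shell` (per-class named vectors): Gaussian kernel SD of
#'   the corresponding random fields, in mm
#' @param prostate_axes_mm in-plane semi-axes of the prostate ellipse in mm
#' @param lesion_radius_mm range (min, max) of lesion in-plane radius in mm
#' @param lesion_thickness_factor range of the lesion through-plane
#'   semi-axis as a multiple of the slice thickness; the default
#'   `c(0.6, 1.4)` gives lesions spanning 1-3 slices
#' @param lesion_placement "random" or "center" (lesion centred in the
#'   gland; used for controlled geometry tests)
#' @param pirads_noise probability that the PI-RADS score is drawn
#'   uniformly from 1..5 instead of from the risk-consistent mapping
#' @param seed integer cohort seed
#' @return a validated `phantom_config` object (a list)
#' @export
phantom_config <- function(image_size = 96,
                           pixel_spacing = 0.5,
                           slice_thickness = 3,
                           n_slices_range = c(3L, 7L),
                           n_patients = 40,
                           lesions_per_patient = c("1" = 0.7, "2" = 0.3),
                           class_mix = c(L = 1 / 3, I = 1 / 3, H = 1 / 3),
                           it_effect = c(L = 0, I = 0.6, H = 1.2),
                           it_sequences = c("T2W", "ADC"),
                           pt_effect = outer(c(L = 0, I = 0.4, H = 0.8),
                                             c(1, 0.75, 0.5, 0.25)),
                           pt_sequences = c("T2W", "ADC"),
                           adc_shift = c(L = 0, I = -1, H = -2),
                           noise_sd = list(t2w = 40, adc = 0.12),
                           correlation_length_mm = list(
                             background = 0.8,
                             lesion = c(L = 0.8, I = 1.2, H = 1.6),
                             shell = c(L = 0.8, I = 1.2, H = 1.6)),
                           prostate_axes_mm = c(19, 15),
                           lesion_radius_mm = c(3, 5),
                           lesion_thickness_factor = c(0.6, 1.4),
                           lesion_placement = c("random", "center"),
                           pirads_noise = 0.2,
                           seed = 1L) {
  lesion_placement <- match.arg(lesion_placement)
  stopifnot(image_size >= 16, pixel_spacing > 0, slice_thickness > 0,
            length(n_slices_range) == 2, n_slices_range[1] >= 2,
            n_patients >= 1, length(prostate_axes_mm) == 2,
            all(prostate_axes_mm > 0), length(lesion_radius_mm) == 2,
            pirads_noise >= 0, pirads_noise <= 1)
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop_radpt("radpt_config_error", "class_mix must sum to 1")
  if (!all(c("L", "I", "H") %in% names(class_mix)))
    stop_radpt("radpt_config_error", "class_mix needs names L, I, H")
  if (!all(is.finite(it_effect)) || !all(is.finite(pt_effect)) ||
      !all(is.finite(adc_shift)))
    stop_radpt("radpt_config_error", "effect sizes must be finite")
  pt_effect <- as.matrix(pt_effect)
  if (!all(dim(pt_effect) == c(3, 4)))
    stop_radpt("radpt_config_error", "pt_effect must be 3 classes x 4 bands")
  rownames(pt_effect) <- c("L", "I", "H")
  # the rings are clipped to the prostate, so the image only needs to hold
  # the gland plus a small margin
  if (image_size * pixel_spacing / 2 < max(prostate_axes_mm) + 2)
    stop_radpt("radpt_config_error",
               "image too small to contain the prostate (+2 mm margin)")
  if (min(prostate_axes_mm) <= min(lesion_radius_mm))
    stop_radpt("radpt_geometry_error",
               "lesion cannot fit inside the prostate")
  cfg <- list(image_size = as.integer(image_size),
              pixel_spacing = pixel_spacing,
              slice_thickness = slice_thickness,
              n_slices_range = as.integer(n_slices_range),
              n_patients = as.integer(n_patients),
              lesions_per_patient = lesions_per_patient,
              class_mix = class_mix[c("L", "I", "H")],
              it_effect = it_effect, it_sequences = it_sequences,
              pt_effect = pt_effect, pt_sequences = pt_sequences,
              adc_shift = adc_shift, noise_sd = noise_sd,
              correlation_length_mm = correlation_length_mm,
              prostate_axes_mm = prostate_axes_mm,
              lesion_radius_mm = lesion_radius_mm,
              lesion_thickness_factor = lesion_thickness_factor,
              lesion_placement = lesion_placement,
              pirads_noise = pirads_noise,
              seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  cfg
}

#' Null-effect phantom configuration
#'
#' Convenience wrapper: all class effects (texture, ADC shift) are zero and
#' correlation lengths are identical across classes, so class-conditional
#' feature distributions are identical up to sampling noise and any
#' downstream classifier is expected to perform at chance.
#'
#' @param ... overrides passed on to [phantom_config()]
#' @export
phantom_config_null <- function(...) {
  phantom_config(it_effect = c(L = 0, I = 0, H = 0),
                 pt_effect = matrix(0, 3, 4),
                 adc_shift = c(L = 0, I = 0, H = 0),
                 correlation_length_mm = list(
                   background = 0.8,
                   lesion = c(L = 0.8, I = 0.8, H = 0.8),
                   shell = c(L = 0.8, I = 0.8, H = 0.8)),
                 ...)
}

#' Assign a synthetic PI-RADS v2 score to a risk label
#'
#' With probability `1 - pirads_noise`, low-risk maps to scores 1-2,
#' intermediate to 3, and high to 4-5 (the binarization used downstream
#' groups 1-2 as "low" and 3-5 as "high" likelihood); otherwise the score
#' is drawn uniformly from 1..5. Draws use the current RNG state.
#'
#' @param risk_label one of "L", "I", "H"
#' @param pirads_noise mis-grading probability in `[0, 1]`
#' @return integer score in 1..5
#' @export
assign_pirads <- function(risk_label, pirads_noise) {
  if (!risk_label %in% c("L", "I", "H"))
    stop_radpt("radpt_input_error", "invalid risk label '%s'", risk_label)
  if (pirads_noise < 0 || pirads_noise > 1)
    stop_radpt("radpt_input_error", "pirads_noise must be in [0, 1]")
  if (runif(1) < pirads_noise) return(sample(1:5, 1))
  switch(risk_label,
         L = sample(1:2, 1),
         I = 3L,
         H = sample(4:5, 1))
}

# per-slice elliptical prostate cross-sections of an ellipsoid whose
# through-plane semi-axis slightly exceeds the stack so end slices keep gland
phantom_prostate_mask <- function(cfg, n_slices) {
  n <- cfg$image_size
  s <- cfg$pixel_spacing
  cx <- (n - 1) / 2 * s
  xs <- ((seq_len(n) - 1) * s - cx)
  zc <- (n_slices - 1) / 2
  cz <- (n_slices * cfg$slice_thickness) / 2 * 1.15
  mask <- array(FALSE, dim = c(n, n, n_slices))
  for (z in seq_len(n_slices)) {
    dz <- (z - 1 - zc) * cfg$slice_thickness
    shrink <- sqrt(max(0, 1 - (dz / cz)^2))
    a <- cfg$prostate_axes_mm[1] * shrink
    b <- cfg$prostate_axes_mm[2] * shrink
    if (a < s || b < s) next
    mask[, , z] <- outer(xs, xs, function(x, y) (x / a)^2 + (y / b)^2 <= 1)
  }
  mask
}

# depth (mm) of each in-slice prostate pixel from the gland boundary
prostate_depth <- function(prostate_slice, spacing) {
  out <- .edt_mm_cpp(matrix(as.integer(!prostate_slice),
                            nrow(prostate_slice)),
                     spacing, spacing)
  out[!prostate_slice] <- 0
  out
}

phantom_lesion_mask <- function(cfg, prostate, existing, n_slices) {
  n <- cfg$image_size
  s <- cfg$pixel_spacing
  zc <- ceiling(n_slices / 2)
  depth <- prostate_depth(prostate[, , zc], s)
  r <- runif(1, cfg$lesion_radius_mm[1], cfg$lesion_radius_mm[2])
  max_depth <- max(depth)
  if (max_depth < cfg$lesion_radius_mm[1])
    stop_radpt("radpt_geometry_error",
               "lesion cannot fit inside the prostate")
  r <- min(r, max_depth - 0.5 * s)
  ok <- depth >= r + s
  if (cfg$lesion_placement == "center") {
    # most interior pixel
    idx <- which(depth == max_depth, arr.ind = TRUE)[1, ]
  } else {
    # keep >= 3 mm clearance from other lesions when possible
    if (length(existing)) {
      other <- Reduce(`|`, lapply(existing, function(m) m[, , zc]))
      if (any(other)) {
        do <- .edt_mm_cpp(matrix(as.integer(other), n), s, s)
        ok2 <- ok & (do >= r + 3)
        if (!any(ok2)) ok2 <- ok & (do >= r + s)  # relax clearance
        if (any(ok2)) ok <- ok2
      }
    }
    if (!any(ok)) ok <- depth >= max(r, max_depth * 0.8)
    cand <- which(ok, arr.ind = TRUE)
    idx <- cand[sample(nrow(cand), 1), ]
  }
  cx <- (idx[1] - 1) * s
  cy <- (idx[2] - 1) * s
  # blob: disc with angularly-modulated radius from a smooth shape field,
  # extruded through-plane as an ellipsoid cross-section
  shape <- unit_grf(n, n, 2 / s)
  cz_mm <- cfg$slice_thickness * runif(1, cfg$lesion_thickness_factor[1],
                                       cfg$lesion_thickness_factor[2])
  xs <- (seq_len(n) - 1) * s
  dist2 <- outer((xs - cx)^2, (xs - cy)^2, `+`)
  mask <- array(FALSE, dim = c(n, n, n_slices))
  for (z in seq_len(n_slices)) {
    dz <- (z - zc) * cfg$slice_thickness
    f <- 1 - (dz / cz_mm)^2
    if (f <= 0) next
    rz <- r * sqrt(f)
    local_r <- rz * (1 + 0.25 * shape)
    mask[, , z] <- (dist2 <= pmax(local_r, 0)^2) & prostate[, , z]
  }
  if (length(existing))
    for (m in existing) mask <- mask & !m
  if (!any(mask))
    stop_radpt("radpt_geometry_error",
               "lesion cannot fit inside the prostate")
  mask
}

# smooth anatomical base intensities for one slice
phantom_base <- function(cfg, prostate_slice, channel) {
  n <- cfg$image_size
  s <- cfg$pixel_spacing
  cx <- (n - 1) / 2 * s
  xs <- ((seq_len(n) - 1) * s - cx)
  radial <- outer((xs / cfg$prostate_axes_mm[1])^2,
                  (xs / cfg$prostate_axes_mm[2])^2, `+`)
  if (channel == "t2w") {
    base <- matrix(300, n, n)
    base[prostate_slice] <- 450 + 60 * (1 - radial[prostate_slice])
  } else {
    base <- matrix(0.9, n, n)
    base[prostate_slice] <- 1.35 + 0.15 * (1 - radial[prostate_slice])
  }
  base
}

#' Generate one synthetic patient study
#'
#' Deterministic given `(config$seed, patient_index)`. Produces co-registered
#' T2W and ADC grids, a prostate mask, and 1-2 lesions with risk labels and
#' PI-RADS scores. Texture is stationary correlated noise; class effects are
#' added inside each lesion and in its 3 mm peri-tumoral bands (computed in
#' 2D per slice, clipped to the prostate) with band-specific strength.
#'
#' @param config a [phantom_config()]
#' @param patient_index 1-based patient index (`<= config$n_patients`)
#' @return a `radpt_study`: list with `patient_id`, `t2w`, `adc` (3D arrays
#'   with rows/cols in-plane and slices third), `spacing` (mm per pixel,
#'   in-plane), `slice_thickness`, `prostate_mask`, and `lesions` (each a
#'   list with `lesion_id`, `mask`, `risk`, `pirads`)
#' @export
generate_study <- function(config, patient_index) {
  stopifnot(inherits(config, "phantom_config"))
  if (patient_index < 1 || patient_index > config$n_patients)
    stop_radpt("radpt_input_error", "patient_index out of range")
  pseed <- (config$seed %% 100000L) * 20011L + patient_index * 7919L
  pseed <- pseed %% 2147483647L
  with_seed(pseed, {
    n <- config$image_size
    s <- config$pixel_spacing
    n_slices <- sample(seq(config$n_slices_range[1],
                           config$n_slices_range[2]), 1)
    prostate <- phantom_prostate_mask(config, n_slices)
    n_lesions <- as.integer(sample(names(config$lesions_per_patient), 1,
                                   prob = config$lesions_per_patient))
    lesions <- list()
    masks <- list()
    for (li in seq_len(n_lesions)) {
      risk <- sample(names(config$class_mix), 1, prob = config$class_mix)
      mask <- phantom_lesion_mask(config, prostate, masks, n_slices)
      masks[[li]] <- mask
      lesions[[li]] <- list(
        lesion_id = sprintf("P%03d_L%d", patient_index, li),
        mask = mask, risk = risk,
        pirads = assign_pirads(risk, config$pirads_noise))
    }
    all_lesion <- Reduce(`|`, masks)
    t2w <- array(0, dim = c(n, n, n_slices))
    adc <- array(0, dim = c(n, n, n_slices))
    corr_bg_px <- config$correlation_length_mm$background / s
    sds <- c(t2w = config$noise_sd$t2w, adc = config$noise_sd$adc)
    # per-lesion peri-tumoral band masks (2D distance per slice)
    band_masks <- lapply(masks, function(m) {
      bands <- vector("list", 4)
      d <- array(Inf, dim = dim(m))
      for (z in seq_len(n_slices)) {
        if (!any(m[, , z])) next
        d[, , z] <- .edt_mm_cpp(matrix(as.integer(m[, , z]), n), s, s)
      }
      for (b in 1:4)
        bands[[b]] <- (d > (b - 1) * 3) & (d <= b * 3) & prostate & !all_lesion
      bands
    })
    for (z in seq_len(n_slices)) {
      pz <- prostate[, , z]
      for (ch in c("t2w", "adc")) {
        seqname <- if (ch == "t2w") "T2W" else "ADC"
        img <- phantom_base(config, pz, ch) +
          sds[[ch]] * unit_grf(n, n, corr_bg_px)
        for (li in seq_along(masks)) {
          risk <- lesions[[li]]$risk
          lm <- masks[[li]][, , z]
          e <- config$it_effect[[risk]]
          if (any(lm) && e != 0 && seqname %in% config$it_sequences) {
            f <- unit_grf(n, n, config$correlation_length_mm$lesion[[risk]] / s)
            img[lm] <- img[lm] + sds[[ch]] * e * f[lm]
          }
          if (seqname %in% config$pt_sequences) {
            fsh <- NULL
            for (b in 1:4) {
              eb <- config$pt_effect[risk, b]
              bm <- band_masks[[li]][[b]][, , z]
              if (eb != 0 && any(bm)) {
                if (is.null(fsh))
                  fsh <- unit_grf(n, n,
                                  config$correlation_length_mm$shell[[risk]] / s)
                img[bm] <- img[bm] + sds[[ch]] * eb * fsh[bm]
              }
            }
          }
          if (ch == "adc" && any(lm))
            img[lm] <- img[lm] + sds[[ch]] * config$adc_shift[[risk]]
        }
        if (ch == "t2w") t2w[, , z] <- img else adc[, , z] <- img
      }
    }
    structure(list(patient_id = sprintf("P%03d", patient_index),
                   t2w = t2w, adc = adc,
                   spacing = c(s, s),
                   slice_thickness = config$slice_thickness,
                   prostate_mask = prostate,
                   lesions = lesions),
              class = "radpt_study")
  })
}

#' Generate a full phantom cohort
#'
#' Calls [generate_study()] for every patient and assembles the lesion
#' manifest. Deterministic given the config (including its seed). When
#' `out_dir` is given, studies are written as RDS files (one per patient;
#' a stand-in for NIfTI, which has no reader in this R environment) along
#' with `manifest.csv`.
#'
#' @param config a [phantom_config()]
#' @param out_dir optional output directory
#' @return list with `studies` (list of `radpt_study`) and `manifest`
#'   (data.frame: patient_id, lesion_id, risk, pirads, n_slices)
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  studies <- lapply(seq_len(config$n_patients),
                    function(i) generate_study(config, i))
  manifest <- do.call(rbind, lapply(studies, function(st) {
    do.call(rbind, lapply(st$lesions, function(l) {
      data.frame(patient_id = st$patient_id, lesion_id = l$lesion_id,
                 risk = l$risk, pirads = l$pirads,
                 n_slices = dim(st$t2w)[3], stringsAsFactors = FALSE)
    }))
  }))
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (st in studies)
      saveRDS(st, file.path(out_dir, paste0(st$patient_id, ".rds")))
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  list(studies = studies, manifest = manifest)
}
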