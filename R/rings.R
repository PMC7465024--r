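#' Euclidean distance from the lesion (mm)
#'
#' Exact Euclidean distance transform of the lesion complement, scaled by
#' the per-axis pixel spacing; 0 inside the lesion. Distances are computed
#' in 2D per slice (the texture battery is 2D); slices without lesion
#' pixels get `Inf` everywhere.
#'
#' @param lesion_mask logical matrix or 3D array
#' @param spacing in-plane spacing in mm (scalar or length-2)
#' @return distance grid of the same shape, in mm
#' @export
distance_from_lesion <- function(lesion_mask, spacing) {
  if (!any(lesion_mask))
    stop_radpt("radpt_input_error", "empty lesion mask")
  spacing <- rep(spacing, length.out = 2)
  one <- function(m)
    .edt_mm_cpp(matrix(as.integer(m), nrow(m)), spacing[1], spacing[2])
  if (length(dim(lesion_mask)) == 3) {
    out <- array(Inf, dim = dim(lesion_mask))
    for (z in seq_len(dim(lesion_mask)[3]))
      if (any(lesion_mask[, , z]))
        out[, , z] <- one(lesion_mask[, , z])
    out
  } else {
    one(lesion_mask)
  }
}

#' Build the intra-tumoral ROI and the annular peri-tumoral ring masks
#'
#' Ring k covers distances in the half-open interval
#' `((k-1) * width, k * width]` mm from the lesion boundary (Euclidean, 2D
#' per slice), intersected with the prostate and excluding the target
#' lesion and any other lesion of the same patient. With defaults this
#' yields the four 3 mm bands 0-3, 3-6, 6-9, 9-12 mm. Rings may be empty
#' near the gland edge.
#'
#' @param lesion_mask logical grid (the target lesion)
#' @param prostate_mask logical grid
#' @param other_lesion_masks list of logical grids (may be empty)
#' @param spacing in-plane spacing in mm
#' @param ring_width_mm band width in mm (default 3)
#' @param n_rings number of bands (default 4)
#' @return a `ring_set`: list with `it_mask`, `rings` (list of lists with
#'   `lower_mm`, `upper_mm`, `mask`), `spacing`
#' @export
build_rings <- function(lesion_mask, prostate_mask,
                        other_lesion_masks = list(), spacing,
                        ring_width_mm = 3, n_rings = 4) {
  if (any(spacing <= 0))
    stop_radpt("radpt_input_error", "spacing must be positive")
  if (any(lesion_mask & !prostate_mask))
    stop_radpt("radpt_mask_error", "lesion mask is not inside the prostate")
  d <- distance_from_lesion(lesion_mask, spacing)
  excl <- lesion_mask
  for (m in other_lesion_masks) excl <- excl | m
  rings <- lapply(seq_len(n_rings), function(k) {
    lo <- (k - 1) * ring_width_mm
    hi <- k * ring_width_mm
    mask <- (d > lo) & (d <= hi) & prostate_mask & !excl
    list(lower_mm = lo, upper_mm = hi, mask = mask)
  })
  structure(list(it_mask = lesion_mask, rings = rings, spacing = spacing),
            class = "ring_set")
}

#' Ring sets for every lesion of a study
#'
#' @param study a `radpt_study`
#' @param ring_width_mm,n_rings see [build_rings()]
#' @return list of `ring_set`, one per lesion, in lesion order
#' @export
study_ring_sets <- function(study, ring_width_mm = 3, n_rings = 4) {
  masks <- lapply(study$lesions, `[[`, "mask")
  lapply(seq_along(masks), function(i) {
    build_rings(masks[[i]], study$prostate_mask,
                masks[-i], study$spacing, ring_width_mm, n_rings)
  })
}
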