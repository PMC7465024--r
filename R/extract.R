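#' Texture feature battery definition
#'
#' The default battery per sequence per ROI is 1 signal + 9 first-order +
#' 76 Gabor + 39 Haralick (3 window sizes x 13 statistics) + 25 Laws =
#' 150 features (aggregated with the mean by default). CoLlAGe (13 more)
#' is an optional extension kept off by default to preserve the printed
#' 150/300/1200 column counts. The `"mini"` battery (56 features) is a
#' scaled-down battery for simulation-heavy property tests.
#'
#' @param name "default" or "mini"
#' @param include_collage add the 13 CoLlAGe features
#' @return data.frame with columns `family`, `param`
#' @export
texture_battery <- function(name = c("default", "mini"),
                            include_collage = FALSE) {
  name <- match.arg(name)
  hstats <- haralick_stat_names()
  if (name == "default") {
    gab <- names(gabor_bank())
    har <- as.vector(t(outer(paste0("w", c(3, 5, 7)), hstats,
                             paste, sep = "_")))
  } else {
    gab <- names(gabor_bank(wavelengths = c(3, 5), n_orientations = 4,
                            allow_any_bank = TRUE))
    har <- paste0("w5_", hstats)
  }
  fo <- c("mean3", "median3", "sd3", "range3", "sobelx", "sobely",
          "sobelmag", "mean5", "median5")
  spec <- rbind(
    data.frame(family = "signal", param = "raw"),
    data.frame(family = "fo", param = fo),
    data.frame(family = "gabor", param = gab),
    data.frame(family = "haralick", param = har),
    data.frame(family = "laws", param = names(laws_kernels())))
  if (include_collage)
    spec <- rbind(spec,
                  data.frame(family = "collage", param = paste0("w5_", hstats)))
  spec
}

roi_names <- function() c("IT", "PT_0_3", "PT_3_6", "PT_6_9", "PT_9_12")

#' Canonical feature name
#'
#' `"<sequence>.<roi>.<family>.<param>.<aggregator>"`, e.g.
#' `"T2W.PT_3_6.haralick.w5_sum_entropy.mean"`. Fields never contain dots,
#' so names are uniquely parseable.
#'
#' @param sequence "T2W" or "ADC"
#' @param roi one of `roi_names()`
#' @param family,param battery fields
#' @param aggregator aggregation statistic
#' @export
feature_name <- function(sequence, roi, family, param, aggregator = "mean")
  paste(sequence, roi, family, param, aggregator, sep = ".")

#' Parse canonical feature names back into their fields
#'
#' @param names character vector of canonical feature names
#' @return data.frame with columns sequence, roi, family, param, aggregator
#' @export
parse_feature_name <- function(names) {
  parts <- strsplit(names, ".", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 5L
  if (any(bad))
    stop_radpt("radpt_input_error", "unparseable feature name '%s'",
               names[bad][1])
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- c("sequence", "roi", "family", "param", "aggregator")
  out
}

# collect ROI-masked map values pooled across slices, then aggregate
pool_and_aggregate <- function(pools, aggregators) {
  unlist(lapply(aggregators, function(a) {
    v <- pools[is.finite(pools)]
    if (!length(v)) NA_real_ else moment_stat(v, a)
  }))
}

#' Extract the full texture feature battery for one study
#'
#' For every lesion: the study is cropped to the lesion plus the 12 mm
#' shell plus 2 mm padding; every battery feature is computed per slice as
#' a 2D response map, masked by each ROI (intra-tumoral and the four 3 mm
#' peri-tumoral rings), pooled across slices, and aggregated. With the
#' default battery and `aggregators = "mean"` this gives 150 features per
#' sequence per ROI: 300 intra-tumoral and 1200 peri-tumoral columns per
#' lesion across both sequences.
#'
#' @param study a (preprocessed) `radpt_study`
#' @param ring_sets optional list of `ring_set` (one per lesion); computed
#'   with [study_ring_sets()] when `NULL`
#' @param battery a [texture_battery()] data.frame or a battery name
#' @param aggregators subset of mean, sd, skewness, kurtosis; each extra
#'   aggregator multiplies the column count
#' @param n_levels Haralick quantization depth
#' @return data.frame: `patient_id`, `lesion_id`, `risk`, `pirads`, then
#'   one numeric column per feature (canonical names); empty-ROI cells are
#'   `NA`
#' @export
extract_all <- function(study, ring_sets = NULL, battery = "default",
                        aggregators = "mean", n_levels = 64) {
  if (is.character(battery)) battery <- texture_battery(battery)
  if (is.null(ring_sets)) ring_sets <- study_ring_sets(study)
  stopifnot(length(ring_sets) == length(study$lesions))
  aggregators <- match.arg(aggregators,
                           c("mean", "sd", "skewness", "kurtosis"),
                           several.ok = TRUE)
  fam_params <- split(battery$param, battery$family)
  use_gabor <- !is.null(fam_params$gabor)
  bank <- if (use_gabor) {
    all_bank <- gabor_bank(allow_any_bank = TRUE,
                           wavelengths = c(3, 4, 5, 6), n_orientations = 19)
    missing <- setdiff(fam_params$gabor, names(all_bank))
    if (length(missing))
      all_bank <- c(all_bank, gabor_bank(wavelengths = c(3, 5),
                                         n_orientations = 4,
                                         allow_any_bank = TRUE))
    all_bank[fam_params$gabor]
  }
  har_windows <- if (!is.null(fam_params$haralick))
    sort(unique(as.integer(sub("^w(\\d+)_.*$", "\\1",
                               fam_params$haralick))))
  spacing <- study$spacing
  rows <- vector("list", length(study$lesions))
  colnames_out <- NULL
  for (li in seq_along(study$lesions)) {
    lesion <- study$lesions[[li]]
    rs <- ring_sets[[li]]
    cr <- crop_to_roi(study$t2w, lesion$mask, 12 + 2, spacing)
    off <- cr$offset
    nr <- dim(cr$image)[1]; nc <- dim(cr$image)[2]
    ri <- seq_len(nr) + off[1]; ci <- seq_len(nc) + off[2]
    imgs <- list(T2W = cr$image, ADC = study$adc[ri, ci, , drop = FALSE])
    rois <- c(list(IT = rs$it_mask[ri, ci, , drop = FALSE]),
              stats::setNames(lapply(rs$rings, function(r)
                r$mask[ri, ci, , drop = FALSE]), roi_names()[-1]))
    nz <- dim(imgs$T2W)[3]
    plane <- nr * nc
    # slices where any ROI is nonempty
    keep <- which(vapply(seq_len(nz), function(z)
      any(vapply(rois, function(m) any(m[, , z]), logical(1))), logical(1)))
    # per-family plane index of each battery row (position in the 3D maps)
    fam_plane <- integer(nrow(battery))
    fo_names <- c("mean3", "median3", "sd3", "range3", "sobelx", "sobely",
                  "sobelmag", "mean5", "median5")
    for (fi in seq_len(nrow(battery))) {
      fam_plane[fi] <- switch(battery$family[fi],
        signal = 0L,
        fo = match(battery$param[fi], fo_names),
        gabor = match(battery$param[fi], names(bank)),
        haralick = match(battery$param[fi],
                         as.vector(t(outer(paste0("w", har_windows),
                                           haralick_stat_names(),
                                           paste, sep = "_")))),
        laws = match(battery$param[fi], names(laws_kernels())),
        collage = match(battery$param[fi],
                        paste0("w5_", haralick_stat_names())))
    }
    vals <- c()
    nms <- c()
    for (sq in c("T2W", "ADC")) {
      # pooled masked values: [[roi]][[feature]] -> numeric vector
      pools <- lapply(rois, function(x)
        lapply(seq_len(nrow(battery)), function(i) numeric(0)))
      for (z in keep) {
        sl <- imgs[[sq]][, , z]
        roi_sl <- lapply(rois, function(m) m[, , z])
        if (!any(vapply(roi_sl, any, logical(1)))) next
        any_mask <- Reduce(`|`, roi_sl)
        fo <- if (!is.null(fam_params$fo) || !is.null(fam_params$signal))
          first_order_maps(sl, any_mask)
        gvec <- if (use_gabor) as.vector(gabor_maps(sl, bank))
        lvec <- if (!is.null(fam_params$laws)) as.vector(laws_maps(sl))
        fvec <- if (!is.null(fo)) as.vector(fo$maps)
        for (rn in names(roi_sl)) {
          m <- roi_sl[[rn]]
          if (!any(m)) next
          idx <- which(m)
          hvec <- if (!is.null(fam_params$haralick))
            as.vector(haralick_maps(sl, m, har_windows, n_levels))
          cvec <- if (!is.null(fam_params$collage))
            as.vector(collage_maps(sl, m, 5, 64))
          for (fi in seq_len(nrow(battery))) {
            k <- fam_plane[fi]
            mv <- switch(battery$family[fi],
              signal = sl[idx],
              fo = fvec[(k - 1L) * plane + idx],
              gabor = gvec[(k - 1L) * plane + idx],
              haralick = hvec[(k - 1L) * plane + idx],
              laws = lvec[(k - 1L) * plane + idx],
              collage = cvec[(k - 1L) * plane + idx])
            pools[[rn]][[fi]] <- c(pools[[rn]][[fi]], mv)
          }
        }
      }
      for (rn in names(pools)) {
        for (fi in seq_len(nrow(battery))) {
          v <- pool_and_aggregate(pools[[rn]][[fi]], aggregators)
          vals <- c(vals, v)
          if (li == 1)
            nms <- c(nms, feature_name(sq, rn, battery$family[fi],
                                       battery$param[fi], aggregators))
        }
      }
    }
    if (is.null(colnames_out)) colnames_out <- nms
    rows[[li]] <- c(list(patient_id = study$patient_id,
                         lesion_id = lesion$lesion_id,
                         risk = lesion$risk,
                         pirads = lesion$pirads),
                    as.list(stats::setNames(vals, colnames_out)))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  rownames(out) <- NULL
  attr(out, "meta_cols") <- c("patient_id", "lesion_id", "risk", "pirads")
  out
}

#' Extract features for every study of a cohort
#'
#' @param studies list of `radpt_study`
#' @inheritParams extract_all
#' @return row-bound [extract_all()] tables
#' @export
extract_cohort <- function(studies, battery = "default",
                           aggregators = "mean", n_levels = 64) {
  if (is.character(battery)) battery <- texture_battery(battery)
  out <- do.call(rbind, lapply(studies, function(st)
    extract_all(st, NULL, battery, aggregators, n_levels)))
  rownames(out) <- NULL
  attr(out, "meta_cols") <- c("patient_id", "lesion_id", "risk", "pirads")
  out
}

#' Feature column names of a feature table
#'
#' @param table a feature table from [extract_all()]
#' @export
feature_cols <- function(table)
  setdiff(names(table),
          union(attr(table, "meta_cols") %||% character(0),
                c("patient_id", "lesion_id", "risk", "pirads", "cohort")))
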