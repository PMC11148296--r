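#' Feature-extraction configuration
#'
#' @param sigma_mm Laplacian-of-Gaussian scales in mm.
#' @param bin_width Fixed gray-level bin width on normalized units.
#' @param norm_scale Rescaling applied after z-scoring (see
#'   [normalize_mu3sigma()]).
#' @param norm_k Outlier clip in standard deviations.
#' @param target_spacing Isotropic resampling target in mm.
#' @param wavelet Logical; include the 8 wavelet subband images.
#' @return An `extract_config` list.
#' @export
extract_config <- function(sigma_mm = c(2, 4), bin_width = 5,
                           norm_scale = 100, norm_k = 3,
                           target_spacing = c(1, 1, 1), wavelet = TRUE) {
  structure(list(sigma_mm = sigma_mm, bin_width = bin_width,
                 norm_scale = norm_scale, norm_k = norm_k,
                 target_spacing = rep(target_spacing, length.out = 3),
                 wavelet = wavelet),
            class = "extract_config")
}

.sigma_tag <- function(s)
  sprintf("log_sigma_%s_mm_3D", gsub("\\.", "_", format(s, nsmall = 1)))

#' Extract the full feature vector of one study
#'
#' Runs the standard extraction pipeline on the first post-contrast phase
#' restricted to a malignant-subregion mask: normalize (whole volume,
#' mean +/- 3 sigma rule), resample to the isotropic target grid (cubic
#' for the image, nearest-neighbor for the mask), derive the filtered
#' images (Laplacian-of-Gaussian per sigma; the 8 wavelet subbands), then
#' for each image discretize the masked intensities at the fixed bin
#' width and compute the 18 first-order and 24 direction-averaged GLCM
#' features. Shape features are computed once, from the resampled mask.
#' Feature names follow `<image>_<family>_<name>` with image `original`,
#' `log_sigma_<s>_mm_3D` or `wavelet_<band>`.
#'
#' @param study A `dce_study`.
#' @param mask Binary malignant mask on the study grid; default derives
#'   it via [build_subregion_map()] and [malignant_mask()].
#' @param config An [extract_config()].
#' @return Named numeric vector (14 shape + 42 per image).
#' @export
extract_study_features <- function(study, mask = NULL,
                                   config = extract_config()) {
  stopifnot(inherits(study, "dce_study"))
  if (is.null(mask)) mask <- malignant_mask(build_subregion_map(study))
  if (!any(mask)) stop("empty malignant subregion: study excluded")
  first <- study$phases[[2]]
  norm <- normalize_mu3sigma(first, scale = config$norm_scale,
                             k = config$norm_k)
  res <- resample_isotropic(norm, study$spacing, mask = mask,
                            target = config$target_spacing)
  vol <- res$volume; msk <- res$mask; sp <- res$spacing

  images <- list(original = vol)
  for (s in config$sigma_mm)
    images[[.sigma_tag(s)]] <- apply_log_filter(vol, sp, s)
  if (config$wavelet) {
    wb <- apply_wavelet_bank(vol)
    names(wb) <- paste0("wavelet_", names(wb))
    images <- c(images, wb)
  }

  shp <- shape_features(msk, sp)
  out <- setNames(shp, paste0("original_shape_", names(shp)))
  vox_vol <- prod(sp)
  for (nm in names(images)) {
    vals <- images[[nm]][msk]
    fo <- firstorder_features(vals, bin_width = config$bin_width,
                              voxel_volume = vox_vol)
    bins_vec <- discretize_fixed_binwidth(vals, config$bin_width)
    bins <- array(0L, dim = dim(msk))
    bins[msk] <- bins_vec
    gl <- glcm_features_averaged(bins, msk,
                                 n_levels = attr(bins_vec, "n_levels"))
    out <- c(out,
             setNames(fo, paste0(nm, "_firstorder_", names(fo))),
             setNames(gl, paste0(nm, "_glcm_", names(gl))))
  }
  out
}

#' Extract features for a cohort of studies
#'
#' Applies [extract_study_features()] to each study; studies whose
#' malignant subregion is empty are excluded and recorded in the
#' `excluded` attribute rather than failing the cohort.
#'
#' @param studies List of `dce_study` objects.
#' @param labels Optional character vector of Ki-67 labels; defaults to
#'   each study's own label.
#' @param config An [extract_config()].
#' @return Tibble with `subject_id`, `label` and one column per feature;
#'   attribute `excluded` lists skipped subject ids.
#' @export
extract_features <- function(studies, labels = NULL,
                             config = extract_config()) {
  ids <- vapply(seq_along(studies), function(i) {
    id <- studies[[i]]$subject_id
    if (is.na(id)) sprintf("sub-%03d", i) else id
  }, character(1))
  if (is.null(labels))
    labels <- vapply(studies, function(s) s$label, character(1))
  rows <- vector("list", length(studies))
  excluded <- character(0)
  for (i in seq_along(studies)) {
    fv <- tryCatch(extract_study_features(studies[[i]], config = config),
                   error = function(e) {
                     if (grepl("empty malignant subregion", conditionMessage(e)))
                       NULL else stop(e)
                   })
    if (is.null(fv)) { excluded <- c(excluded, ids[i]); next }
    rows[[i]] <- fv
  }
  keep <- !vapply(rows, is.null, logical(1))
  mat <- do.call(rbind, rows[keep])
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = ids[keep], label = labels[keep]),
    tibble::as_tibble(mat))
  attr(out, "excluded") <- excluded
  out
}
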