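#' Write a DCE study to NIfTI files
#'
#' One file per phase (`phase_0.nii.gz` for the pre-contrast volume through
#' `phase_6.nii.gz`), plus `voi.nii.gz` (binary mask) and, when ground
#' truth is present, `truth.nii.gz` (integer subregion codes, -1 outside
#' the VOI).
#'
#' @param study A `dce_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_dce_study <- function(study, dir) {
  stopifnot(inherits(study, "dce_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  put <- function(arr, name) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- study$spacing
    path <- file.path(dir, name)
    RNifti::writeNifti(img, path)
    files <<- c(files, path)
  }
  for (p in seq_along(study$phases))
    put(study$phases[[p]], sprintf("phase_%d.nii.gz", p - 1))
  put(study$voi + 0L, "voi.nii.gz")
  if (!is.null(study$truth)) put(study$truth, "truth.nii.gz")
  invisible(files)
}

#' Load a multi-phase DCE series from NIfTI files
#'
#' Reads the phase volumes in the given (time) order together with the
#' lesion VOI mask, validates that all volumes share one grid (shape and
#' spacing), and binarizes the mask (any nonzero voxel is in-VOI).
#'
#' @param phase_paths Character vector of phase volume files, pre-contrast
#'   first, post-contrast phases in acquisition order.
#' @param voi_path Path to the VOI mask file.
#' @param times Phase times in seconds; default assumes the standard
#'   acquisition (plain scan then phases every 60 s).
#' @param label Optional Ki-67 label ("high"/"low") attached to the study.
#' @return A `dce_study`.
#' @export
load_dce_series <- function(phase_paths, voi_path,
                            times = 60 * (seq_along(phase_paths) - 1),
                            label = NA_character_) {
  if (length(phase_paths) < 2)
    stop("need a plain volume plus at least one post-contrast phase")
  vols <- lapply(phase_paths, RNifti::readNifti)
  voi_img <- RNifti::readNifti(voi_path)
  ref_dim <- dim(vols[[1]])
  ref_sp <- RNifti::pixdim(vols[[1]])
  for (v in c(vols[-1], list(voi_img))) {
    if (!identical(dim(v), ref_dim))
      stop("grid mismatch: volumes/mask differ in shape")
    if (max(abs(RNifti::pixdim(v) - ref_sp)) > 1e-4)
      stop("grid mismatch: volumes/mask differ in voxel spacing")
  }
  voi <- array(as.vector(voi_img) != 0, dim = ref_dim)
  if (!any(voi)) stop("degenerate VOI: mask is empty")
  structure(list(
    phases = lapply(vols, function(v) array(as.numeric(v), dim = ref_dim)),
    times = times, voi = voi, truth = NULL, label = label,
    spacing = as.numeric(ref_sp), subject_id = NA_character_),
    class = "dce_study")
}

#' Write a subregion map and its summary
#'
#' Writes the integer-coded subregion labels as NIfTI (`subregions.nii.gz`,
#' -1 outside the VOI) and the per-class voxel counts and fractions as
#' JSON (`subregions.json`).
#'
#' @param map A `subregion_map`.
#' @param dir Output directory.
#' @return Invisibly, the files written.
#' @export
write_subregion_map <- function(map, dir) {
  stopifnot(inherits(map, "subregion_map"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img <- RNifti::asNifti(map$labels)
  RNifti::pixdim(img) <- map$spacing
  nii <- file.path(dir, "subregions.nii.gz")
  RNifti::writeNifti(img, nii)
  js <- file.path(dir, "subregions.json")
  jsonlite::write_json(list(counts = as.list(map$counts),
                            fractions = as.list(map$fractions)),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(nii, js))
}
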