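#' Enhancement ratio between two contrast phases
#'
#' Relative signal change of a comparison phase with respect to a reference
#' phase, \eqn{(SI_{cmp} - SI_{ref}) / SI_{ref}}. The two ratios used for
#' kinetic-curve classification are the first-phase ratio (first
#' post-contrast phase vs the pre-contrast "plain" phase) and the late ratio
#' (last vs first post-contrast phase).
#'
#' Voxels whose reference signal is at or below `eps` have an undefined
#' ratio; they are returned as `-Inf` so that every downstream threshold
#' comparison routes them to the non-enhancing class. No exception is
#' raised; callers count and log such voxels.
#'
#' @param si_ref Reference signal (vector).
#' @param si_cmp Comparison signal (vector, recycled against `si_ref`).
#' @param eps Positive guard below which the reference is treated as zero.
#' @return Numeric vector of dimensionless ratios.
#' @export
enhancement_ratio <- function(si_ref, si_cmp, eps = 1e-12) {
  er <- (si_cmp - si_ref) / si_ref
  er[!(si_ref > eps)] <- -Inf
  er
}

#' Classify voxels by their enhancement curve
#'
#' Implements the voxel-wise kinetic rule: voxels whose first post-contrast
#' enhancement ratio exceeds 50% are enhancing; among those, a late ratio
#' above 10% marks the persistent pattern, below -10% the washout pattern,
#' and the remainder (late ratio within the closed band \[-10%, 10%\]) the
#' plateau pattern. All three threshold comparisons are strict, so both
#' band endpoints fall to plateau.
#'
#' @param si_plain Pre-contrast signal (vector).
#' @param si_first First post-contrast phase signal.
#' @param si_last Last post-contrast phase signal.
#' @param eps_frac Zero-baseline guard as a fraction of `max(si_plain)`;
#'   voxels with plain signal at or below `eps_frac * max(si_plain)` are
#'   labeled non-enhancing.
#' @return Integer vector of labels: 0 non-enhancing, 1 washout, 2 plateau,
#'   3 persistent (see [subregion_levels()]).
#' @export
classify_voxel <- function(si_plain, si_first, si_last, eps_frac = 1e-6) {
  eps <- eps_frac * max(si_plain, 0)
  er_first <- enhancement_ratio(si_plain, si_first, eps = eps)
  er_last <- enhancement_ratio(si_first, si_last, eps = eps)
  lab <- integer(length(er_first))        # 0 = non-enhancing
  enh <- er_first > 0.5
  lab[enh & er_last < -0.1] <- 1L         # washout
  lab[enh & er_last >= -0.1 & er_last <= 0.1] <- 2L  # plateau
  lab[enh & er_last > 0.1] <- 3L          # persistent
  lab
}

#' Subregion label coding
#'
#' @return Named integer vector mapping label names to integer codes.
#' @export
subregion_levels <- function() {
  c(nonenhancing = 0L, washout = 1L, plateau = 2L, persistent = 3L)
}

#' Build the subregion map of a DCE study
#'
#' Applies [classify_voxel()] at every voxel of the lesion VOI using the
#' pre-contrast, first post-contrast and last post-contrast volumes.
#' Classification runs on the native acquisition grid; only the plain,
#' first and last phases enter the rule, so permuting intermediate phases
#' leaves the map unchanged.
#'
#' @param study A `dce_study` (see [generate_study()] / [load_dce_series()]).
#' @return A `subregion_map`: list with `labels` (integer array, codes of
#'   [subregion_levels()], `NA` outside the VOI... see Details), `spacing`,
#'   `counts` (named voxel counts incl. non-enhancing) and `fractions`
#'   (fractions of the VOI).
#' @details `labels` is an integer array of the grid shape with -1 outside
#'   the VOI and the subregion code inside, so that codes 1-3 appear only
#'   within the VOI.
#' @export
build_subregion_map <- function(study) {
  stopifnot(inherits(study, "dce_study"))
  if (length(study$phases) < 3)
    stop("study must have a plain volume and at least 2 post-contrast phases")
  voi <- study$voi
  if (!any(voi)) stop("degenerate VOI: lesion mask is empty")
  plain <- study$phases[[1]]
  first <- study$phases[[2]]
  last <- study$phases[[length(study$phases)]]
  idx <- which(voi)
  lab <- classify_voxel(plain[idx], first[idx], last[idx])
  labels <- array(-1L, dim = dim(voi))
  labels[idx] <- lab
  lev <- subregion_levels()
  counts <- vapply(lev, function(v) sum(lab == v), integer(1))
  structure(
    list(labels = labels, spacing = study$spacing, counts = counts,
         fractions = counts / length(idx)),
    class = "subregion_map")
}

#' Malignant subregion mask
#'
#' The malignant subregion is the union of the washout and plateau
#' subregions. Its voxel count always equals the sum of the two class
#' counts because the subregions are disjoint.
#'
#' @param map A `subregion_map` from [build_subregion_map()].
#' @return Logical array of the grid shape.
#' @export
malignant_mask <- function(map) {
  stopifnot(inherits(map, "subregion_map"))
  mask <- map$labels == 1L | map$labels == 2L
  if (!any(mask))
    stop("empty malignant subregion: no washout or plateau voxels")
  mask
}

#' @export
print.subregion_map <- function(x, ...) {
  cat("subregion map:", paste(dim(x$labels), collapse = "x"), "grid\n")
  cat("  voxel counts:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      "\n")
  invisible(x)
}
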