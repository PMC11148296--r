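#' Intensity normalization by the mean +/- 3 sigma rule
#'
#' Z-scores the whole volume (subtract the global mean, divide by the
#' global standard deviation), rescales by `scale`, then clips values
#' beyond `k` standard deviations to `+/- k * scale`. With the defaults the
#' output lives on a unit where one standard deviation of the input equals
#' 100, making a fixed gray-level bin width of 5 meaningful across
#' subjects.
#'
#' @param volume Numeric 3D array.
#' @param scale Multiplier applied after z-scoring (default 100).
#' @param k Outlier bound in standard deviations (default 3).
#' @return Normalized array of the same shape.
#' @export
normalize_mu3sigma <- function(volume, scale = 100, k = 3) {
  stopifnot(scale > 0, k > 0)
  mu <- mean(volume)
  sigma <- sd(as.vector(volume))
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate intensities: volume has zero variance")
  out <- (volume - mu) / sigma * scale
  out[out > k * scale] <- k * scale
  out[out < -k * scale] <- -k * scale
  out
}

# Catmull-Rom interpolation weight matrix mapping n_old samples at spacing
# sp_old onto n_new samples at spacing sp_new (shared origin, replicated
# edges). Reproduces the input exactly at coincident sample positions.
.interp_matrix_cubic <- function(n_old, sp_old, sp_new, n_new) {
  t <- (seq_len(n_new) - 1) * sp_new / sp_old   # position in old index units
  base <- floor(t)
  u <- t - base
  # Catmull-Rom basis on taps at base + (-1, 0, 1, 2)
  w <- cbind(
    -0.5 * u + u^2 - 0.5 * u^3,
    1 - 2.5 * u^2 + 1.5 * u^3,
    0.5 * u + 2 * u^2 - 1.5 * u^3,
    -0.5 * u^2 + 0.5 * u^3)
  W <- matrix(0, n_new, n_old)
  for (k in 1:4) {
    idx <- pmin(pmax(base + (k - 2L), 0L), n_old - 1L) + 1L
    W[cbind(seq_len(n_new), idx)] <- W[cbind(seq_len(n_new), idx)] + w[, k]
  }
  W
}

.nn_index <- function(n_old, sp_old, sp_new, n_new) {
  t <- (seq_len(n_new) - 1) * sp_new / sp_old
  pmin(pmax(round(t), 0), n_old - 1) + 1L
}

.apply_axis <- function(vol, W, axis) {
  d <- dim(vol)
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  m <- W %*% matrix(v, d[axis], prod(d[-axis]))
  out <- array(m, c(nrow(W), d[perm[2]], d[perm[3]]))
  aperm(out, order(perm))
}

#' Resample a volume and its mask to an isotropic grid
#'
#' The image is interpolated with a separable Catmull-Rom cubic kernel, the
#' mask with nearest-neighbor lookup, onto a grid with the target spacing
#' that shares the input origin and covers the same physical extent to
#' within one voxel.
#'
#' @param volume Numeric 3D array.
#' @param spacing Input voxel spacing, length-3 (mm).
#' @param mask Logical/numeric 3D array on the same grid, or `NULL`.
#' @param target Target spacing, length 1 or 3 (default 1 mm isotropic).
#' @return List with `volume`, `mask` (logical or `NULL`) and `spacing`.
#' @export
resample_isotropic <- function(volume, spacing, mask = NULL,
                               target = c(1, 1, 1)) {
  stopifnot(length(dim(volume)) == 3, all(spacing > 0))
  target <- rep(target, length.out = 3)
  d <- dim(volume)
  n_new <- pmax(1L, as.integer(round(d * spacing / target)))
  out <- volume
  for (ax in 1:3) {
    W <- .interp_matrix_cubic(dim(out)[ax], spacing[ax], target[ax], n_new[ax])
    out <- .apply_axis(out, W, ax)
  }
  m_out <- NULL
  if (!is.null(mask)) {
    idx1 <- .nn_index(d[1], spacing[1], target[1], n_new[1])
    idx2 <- .nn_index(d[2], spacing[2], target[2], n_new[2])
    idx3 <- .nn_index(d[3], spacing[3], target[3], n_new[3])
    m_out <- (mask != 0)[idx1, idx2, idx3, drop = FALSE]
    dim(m_out) <- n_new
    if (!any(m_out))
      stop("degenerate VOI: mask is empty after resampling")
  }
  list(volume = out, mask = m_out, spacing = target)
}

#' Fixed-bin-width gray-level discretization
#'
#' Assigns bin labels `floor((x - min(x)) / width) + 1`, so labels start at
#' 1 and the number of gray levels is the label of the maximum. Invariant
#' to adding a constant to all intensities and equivariant under scaling
#' intensities and width together.
#'
#' @param values Numeric vector of intensities (typically within a mask).
#' @param width Bin width (> 0), default 5.
#' @return Integer vector of bin labels, with attribute `n_levels`.
#' @export
discretize_fixed_binwidth <- function(values, width = 5) {
  stopifnot(width > 0, length(values) > 0)
  bins <- as.integer(floor((values - min(values)) / width)) + 1L
  attr(bins, "n_levels") <- max(bins)
  bins
}
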