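# convolution matrix along one axis with replicated edges
.conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  W <- matrix(0, n, n)
  for (j in seq_along(kernel)) {
    idx <- pmin(pmax(seq_len(n) + (j - r - 1L), 1L), n)
    W[cbind(seq_len(n), idx)] <- W[cbind(seq_len(n), idx)] + kernel[j]
  }
  W
}

#' Laplacian-of-Gaussian filter
#'
#' Band-pass response highlighting blob-like structure at physical scale
#' `sigma` (mm). Implemented as the separable sum of second-derivative-of-
#' Gaussian convolutions: \eqn{G''_x G_y G_z + G_x G''_y G_z + G_x G_y
#' G''_z}, with kernels sampled analytically on the voxel grid (truncated
#' at 4 sigma, replicated edges). The smoothing kernels are normalized to
#' unit sum and the derivative kernels to zero sum, so constant volumes map
#' exactly to zero and linear ramps vanish away from the boundary.
#'
#' @param volume Numeric 3D array.
#' @param spacing Voxel spacing in mm (length 3).
#' @param sigma Filter scale in mm (> 0).
#' @return Filtered array, same shape.
#' @export
apply_log_filter <- function(volume, spacing, sigma) {
  stopifnot(sigma > 0, length(dim(volume)) == 3)
  d <- dim(volume)
  fov <- d * spacing
  if (sigma > min(fov) / 2)
    stop("invalid scale: sigma exceeds half the field of view")
  smooth_k <- deriv_k <- vector("list", 3)
  for (ax in 1:3) {
    h <- spacing[ax]
    r <- max(1L, ceiling(4 * sigma / h))
    x <- (-r:r) * h
    g <- exp(-x^2 / (2 * sigma^2))
    smooth_k[[ax]] <- g / sum(g)
    g2 <- g * (x^2 - sigma^2) / (sigma^4 * sqrt(2 * pi) * sigma) * h
    deriv_k[[ax]] <- g2 - mean(g2)        # exact zero DC response
  }
  out <- array(0, dim = d)
  for (term in 1:3) {
    v <- volume
    for (ax in 1:3) {
      k <- if (ax == term) deriv_k[[ax]] else smooth_k[[ax]]
      v <- .apply_axis(v, .conv_matrix(d[ax], k), ax)
    }
    out <- out + v
  }
  out
}

# Coiflet-1 analysis filters, rescaled to unit low-pass DC gain so the LLL
# subband of a constant volume equals that constant.
.wavelet_filters <- function() {
  lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
          0.852572020212255, 0.337897662457809, -0.072732619512854)
  lo <- lo / sqrt(2)
  n <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(n) - 1)
  list(lo = lo, hi = hi)
}

# circular convolution y[i] = sum_k h[k] x[i - (k-1)] along one axis
.circ_conv_axis <- function(vol, h, axis, adjoint = FALSE) {
  d <- dim(vol)
  n <- d[axis]
  out <- array(0, dim = d)
  for (k in seq_along(h)) {
    s <- if (adjoint) -(k - 1L) else (k - 1L)
    idx <- ((seq_len(n) - 1L - s) %% n) + 1L
    out <- out + h[k] * switch(axis,
      vol[idx, , , drop = FALSE],
      vol[, idx, , drop = FALSE],
      vol[, , idx, drop = FALSE])
  }
  out
}

#' Undecimated single-level 3D wavelet decomposition
#'
#' Separable stationary (same-size) wavelet transform with an orthogonal
#' coiflet-1 filter pair, applied along the z, y and x axes in that order.
#' Subband labels follow the axis order (z, y, x): the first letter is the
#' z-axis filter, the last the x-axis filter, L = low-pass, H = high-pass.
#' Filters are circular (periodic boundary), which makes the decomposition
#' exactly invertible (see [wavelet_reconstruct()]). The low-pass filter is
#' normalized to unit DC gain, so the LLL subband of a constant volume is
#' that constant and every other subband is zero.
#'
#' @param volume Numeric 3D array, at least 8 voxels per axis.
#' @return Named list of 8 arrays (`LLL` ... `HHH`), each the input shape.
#' @export
apply_wavelet_bank <- function(volume) {
  d <- dim(volume)
  stopifnot(length(d) == 3)
  f <- .wavelet_filters()
  if (any(d < max(length(f$lo), 8)))
    stop("decomposition error: volume axis shorter than the filter support")
  bands <- stats::setNames(list(volume), "")
  for (axis in c(3, 2, 1)) {          # letters ordered z, y, x
    nxt <- list()
    for (b in seq_along(bands)) {
      nm <- names(bands)[b]
      nxt[[paste0(nm, "L")]] <- .circ_conv_axis(bands[[b]], f$lo, axis)
      nxt[[paste0(nm, "H")]] <- .circ_conv_axis(bands[[b]], f$hi, axis)
    }
    bands <- nxt
  }
  bands[c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")]
}

#' Invert the undecimated wavelet decomposition
#'
#' Exact inverse of [apply_wavelet_bank()] (perfect reconstruction of the
#' orthogonal pair under periodic convolution).
#'
#' @param bands Named list of the 8 subbands.
#' @return Reconstructed 3D array.
#' @export
wavelet_reconstruct <- function(bands) {
  f <- .wavelet_filters()
  # with DC-gain-1 scaling (filters divided by sqrt(2)), the matched
  # correlation satisfies sum_b conj(H_b) H_b = 1 per axis
  for (axis in c(1, 2, 3)) {
    nxt <- list()
    for (b in seq_along(bands)) {
      nm <- names(bands)[b]
      pos <- 4 - axis                   # letter position for this axis
      letter <- substr(nm, pos, pos)
      h <- if (letter == "L") f$lo else f$hi
      rec <- .circ_conv_axis(bands[[b]], h, axis, adjoint = TRUE)
      key <- substr(nm, 1, pos - 1)
      key <- if (key == "") "root" else key
      nxt[[key]] <- if (is.null(nxt[[key]])) rec else nxt[[key]] + rec
    }
    bands <- nxt
  }
  bands[["root"]]
}
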