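#' The 13 unique 3D direction vectors at Chebyshev distance 1
#'
#' Half of the 26 neighbors of a voxel, one per +/- direction pair;
#' co-occurrences are counted symmetrically so these cover all 26.
#'
#' @return Integer matrix, 13 rows, columns (dx, dy, dz).
#' @export
glcm_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0)))
  unname(g[keep, , drop = FALSE])
}

#' Gray level co-occurrence matrices of a discretized volume
#'
#' Counts pairs of gray levels at each offset, restricted to voxel pairs
#' that both lie inside the mask, symmetrically (each offset and its
#' negation), and normalizes each offset's count matrix to sum 1. Offsets
#' with no valid pair inside the mask are dropped with a warning; if no
#' offset has a valid pair the degenerate 1x1 matrix is returned.
#'
#' @param bins Integer 3D array of gray-level labels (>= 1); values
#'   outside the mask are ignored.
#' @param mask Logical 3D array.
#' @param n_levels Number of gray levels; default `max(bins[mask])`.
#' @param offsets Integer matrix of direction vectors (rows), voxel units.
#' @return List of normalized co-occurrence matrices, one per offset.
#' @export
glcm_compute <- function(bins, mask, n_levels = NULL,
                         offsets = glcm_offsets()) {
  stopifnot(identical(dim(bins), dim(mask)))
  d <- dim(bins)
  if (!any(mask)) stop("glcm requires a nonempty mask")
  midx <- which(mask)
  coord <- arrayInd(midx, d)
  bv <- bins[midx]
  if (is.null(n_levels)) n_levels <- max(bv)
  ng <- as.integer(n_levels)
  out <- vector("list", nrow(offsets))
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    inb <- coord[, 1] + off[1] >= 1L & coord[, 1] + off[1] <= d[1] &
           coord[, 2] + off[2] >= 1L & coord[, 2] + off[2] <= d[2] &
           coord[, 3] + off[3] >= 1L & coord[, 3] + off[3] <= d[3]
    nb <- midx[inb] + off[1] + d[1] * off[2] + d[1] * d[2] * off[3]
    ok <- mask[nb]
    if (!any(ok)) next
    a <- bv[inb][ok]
    b <- bins[nb[ok]]
    cnt <- tabulate((a - 1L) * ng + b, nbins = ng * ng)
    P <- matrix(cnt, ng, ng, byrow = TRUE)
    P <- P + t(P)
    out[[o]] <- P / sum(P)
  }
  keep <- !vapply(out, is.null, logical(1))
  if (!any(keep)) {
    warning("mask has no valid voxel pairs; degenerate 1x1 co-occurrence")
    return(list(matrix(1, 1, 1)))
  }
  if (!all(keep)) warning("some offsets had no valid pairs and were dropped")
  out[keep]
}

#' GLCM texture features
#'
#' The 24 standard co-occurrence features of one normalized, symmetric
#' co-occurrence matrix. Entropies are in bits (log base 2). Degenerate
#' matrices follow the usual conventions: a 1x1 matrix has Idm = 1,
#' ClusterShade = 0, Imc2 = 0, Correlation = 1, MCC = 1.
#'
#' @param P Square co-occurrence probability matrix (entries sum to 1).
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(P) {
  ng <- nrow(P)
  # sparse triplet representation: only nonzero cells contribute to any
  # of the sums below, and masked co-occurrence matrices are sparse
  nz <- which(P > 0)
  pv <- P[nz]
  iv <- ((nz - 1L) %% ng) + 1L
  jv <- ((nz - 1L) %/% ng) + 1L
  px <- rowSums(P); py <- colSums(P)
  lev <- seq_len(ng)
  mu_x <- sum(lev * px); mu_y <- sum(lev * py)
  var_x <- sum((lev - mu_x)^2 * px)
  var_y <- sum((lev - mu_y)^2 * py)
  hxy <- -sum(pv * log2(pv))
  # P(i,j) > 0 implies px(i) > 0 and py(j) > 0
  hxy1 <- -sum(pv * log2(px[iv] * py[jv]))
  pxo <- px[px > 0]; pyo <- py[py > 0]
  hx <- -sum(pxo * log2(pxo))
  hy <- -sum(pyo * log2(pyo))
  # -sum_ij px py (log px + log py) collapses because the marginals sum to 1
  hxy2 <- hx + hy

  dif <- abs(iv - jv)
  p_diff <- numeric(ng)
  acc_d <- rowsum(pv, dif)
  p_diff[as.integer(rownames(acc_d)) + 1L] <- acc_d[, 1]
  k_diff <- 0:(ng - 1)
  p_sum <- numeric(2 * ng - 1)
  acc_s <- rowsum(pv, iv + jv)
  p_sum[as.integer(rownames(acc_s)) - 1L] <- acc_s[, 1]
  k_sum <- 2:(2 * ng)
  da <- sum(k_diff * p_diff)

  corr <- if (var_x > 0 && var_y > 0)
    (sum(iv * jv * pv) - mu_x * mu_y) / sqrt(var_x * var_y) else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - hxy))))

  mcc <- 1
  obs <- px > 0
  if (sum(obs) > 1) {
    Pr <- P[obs, obs, drop = FALSE]
    pxr <- px[obs]
    # Q = Dx^-1 (P Dy^-1 P^T); similar to a symmetric PSD matrix, so the
    # spectrum is real and the second-largest eigenvalue is well defined
    Aq <- Pr %*% (t(Pr) / pxr)
    S <- (1 / sqrt(pxr)) * t((1 / sqrt(pxr)) * t(Aq))
    ev <- sort(eigen((S + t(S)) / 2, symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    mcc <- sqrt(max(0, min(ev[2], 1)))
  }

  ctr <- iv + jv - mu_x - mu_y
  offd <- dif > 0
  c(
    Autocorrelation = sum(iv * jv * pv),
    JointAverage = mu_x,
    ClusterProminence = sum(ctr^4 * pv),
    ClusterShade = sum(ctr^3 * pv),
    ClusterTendency = sum(ctr^2 * pv),
    Contrast = sum(dif^2 * pv),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_diff[p_diff > 0] * log2(p_diff[p_diff > 0])),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(pv / (1 + dif)),
    Idm = sum(pv / (1 + dif^2)),
    Idmn = sum(pv / (1 + dif^2 / ng^2)),
    Idn = sum(pv / (1 + dif / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(pv[offd] / dif[offd]^2),
    JointEnergy = sum(pv^2),
    JointEntropy = hxy,
    MaximumProbability = max(pv),
    MCC = mcc,
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = -sum(p_sum[p_sum > 0] * log2(p_sum[p_sum > 0])),
    SumSquares = var_x)
}

#' Direction-averaged GLCM feature vector
#'
#' Computes [glcm_features()] for each offset matrix and averages feature
#' values over the offsets (the isotropic convention).
#'
#' @inheritParams glcm_compute
#' @return Named numeric vector of 24 direction-averaged features.
#' @export
glcm_features_averaged <- function(bins, mask, n_levels = NULL,
                                   offsets = glcm_offsets()) {
  mats <- glcm_compute(bins, mask, n_levels = n_levels, offsets = offsets)
  rowMeans(vapply(mats, glcm_features, numeric(24)))
}
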