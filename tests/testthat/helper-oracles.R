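# Independent oracle implementations, written from the definitions and
# kept deliberately naive (scalar logic, explicit loops) so they share no
# code path with the package.

# per-voxel kinetic classification as three nested conditionals,
# including the zero-baseline guard (plain <= 1e-6 * max -> non-enhancing)
oracle_classify_one <- function(plain, first, last, eps = 0) {
  if (plain <= eps) return(0L)
  er1 <- (first - plain) / plain
  if (er1 > 0.5) {
    er2 <- (last - first) / first
    if (er2 > 0.1) {
      3L
    } else {
      if (er2 < -0.1) 1L else 2L
    }
  } else {
    0L
  }
}

# brute-force pair enumeration for a single-offset co-occurrence matrix
oracle_glcm_matrix <- function(bins, mask, off, ng) {
  d <- dim(bins)
  M <- matrix(0, ng, ng)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (!mask[x, y, z]) next
    for (s in c(1, -1)) {
      nx <- x + s * off[1]; ny <- y + s * off[2]; nz <- z + s * off[3]
      if (nx < 1 || ny < 1 || nz < 1 || nx > d[1] || ny > d[2] || nz > d[3])
        next
      if (!mask[nx, ny, nz]) next
      M[bins[x, y, z], bins[nx, ny, nz]] <- M[bins[x, y, z], bins[nx, ny, nz]] + 1
    }
  }
  M / sum(M)
}

# definition-by-definition co-occurrence features, all via explicit loops
oracle_glcm_features <- function(P) {
  ng <- nrow(P)
  px <- py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  vx <- sum(((1:ng) - mux)^2 * px); vy <- sum(((1:ng) - muy)^2 * py)
  acc <- function(f) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) if (P[i, j] > 0) s <- s + f(i, j, P[i, j])
    s
  }
  hxy <- -acc(function(i, j, p) p * log2(p))
  hxy1 <- -acc(function(i, j, p) p * log2(px[i] * py[j]))
  hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng)
    if (px[i] * py[j] > 0)
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  pd <- numeric(ng); ps <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  }
  kd <- 0:(ng - 1); ks <- 2:(2 * ng)
  da <- sum(kd * pd)
  Q <- matrix(0, ng, ng)
  for (i in 1:ng) for (j in 1:ng) for (k in 1:ng)
    if (px[i] > 0 && py[k] > 0)
      Q[i, j] <- Q[i, j] + P[i, k] * P[j, k] / (px[i] * py[k])
  obs <- which(px > 0)
  mcc <- 1
  if (length(obs) > 1) {
    ev <- sort(Re(eigen(Q[obs, obs])$values), decreasing = TRUE)
    mcc <- sqrt(max(0, min(1, ev[2])))
  }
  c(
    Autocorrelation = acc(function(i, j, p) i * j * p),
    JointAverage = mux,
    ClusterProminence = acc(function(i, j, p) (i + j - mux - muy)^4 * p),
    ClusterShade = acc(function(i, j, p) (i + j - mux - muy)^3 * p),
    ClusterTendency = acc(function(i, j, p) (i + j - mux - muy)^2 * p),
    Contrast = acc(function(i, j, p) (i - j)^2 * p),
    Correlation = if (vx > 0 && vy > 0)
      (acc(function(i, j, p) i * j * p) - mux * muy) / sqrt(vx * vy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = acc(function(i, j, p) p / (1 + abs(i - j))),
    Idm = acc(function(i, j, p) p / (1 + (i - j)^2)),
    Idmn = acc(function(i, j, p) p / (1 + (i - j)^2 / ng^2)),
    Idn = acc(function(i, j, p) p / (1 + abs(i - j) / ng)),
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - hxy)))),
    InverseVariance = acc(function(i, j, p)
      if (i != j) p / (i - j)^2 else 0),
    JointEnergy = acc(function(i, j, p) p^2),
    JointEntropy = hxy,
    MaximumProbability = max(P),
    MCC = mcc,
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    SumSquares = vx)
}

oracle_firstorder <- function(v, w = 5, vox = 1) {
  n <- length(v)
  mu <- sum(v) / n
  varp <- sum((v - mu)^2) / n
  s <- sqrt(varp)
  bins <- floor((v - min(v)) / w) + 1
  p <- as.numeric(table(bins)) / n
  q <- quantile(v, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  rob <- v[v >= q[1] & v <= q[4]]
  c(Mean = mu, Median = median(v), Minimum = min(v), Maximum = max(v),
    Range = max(v) - min(v), Variance = varp,
    Skewness = if (s > 0) sum((v - mu)^3) / (n * s^3) else 0,
    Kurtosis = if (s > 0) sum((v - mu)^4) / (n * varp^2) else 0,
    Energy = sum(v^2), TotalEnergy = vox * sum(v^2),
    Entropy = -sum(p * log2(p)), Uniformity = sum(p^2),
    RootMeanSquared = sqrt(sum(v^2) / n),
    MeanAbsoluteDeviation = sum(abs(v - mu)) / n,
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    `10Percentile` = q[1], `90Percentile` = q[4],
    InterquartileRange = q[3] - q[2])
}

# O(n^2) pair-counting AUC with ties worth 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "high"]; neg <- scores[labels == "low"]
  s <- 0
  for (a in pos) for (b in neg)
    s <- s + if (a > b) 1 else if (a == b) 0.5 else 0
  s / (length(pos) * length(neg))
}

# plug-in mutual information from an explicit joint histogram (nats)
oracle_mi <- function(xb, yb) {
  n <- length(xb)
  s <- 0
  for (i in unique(xb)) for (j in unique(yb)) {
    pij <- sum(xb == i & yb == j) / n
    if (pij > 0)
      s <- s + pij * log(pij / (sum(xb == i) / n * sum(yb == j) / n))
  }
  s
}

# textbook chi-square statistic (no correction)
oracle_chisq_stat <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# small phantom spec used across tests: scaled-down grid, study conditions
# (fractions, noise, effects) at the generator defaults
test_spec <- function(...) {
  args <- utils::modifyList(
    list(grid = c(28, 28, 20), spacing = c(1, 1, 1.2),
         lesion_semiaxes = c(8, 6, 6)),
    list(...))
  do.call(phantom_spec, args)
}

random_study <- function(seed, d = c(10, 10, 10)) {
  set.seed(seed)
  n <- prod(d)
  phases <- lapply(1:7, function(p)
    array(runif(n, 0, 300), dim = d))
  voi <- array(runif(n) < 0.8, dim = d)
  if (!any(voi)) voi[1] <- TRUE
  structure(list(phases = phases, times = 60 * 0:6, voi = voi, truth = NULL,
                 label = "low", spacing = c(1, 1, 1), subject_id = "r"),
            class = "dce_study")
}
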