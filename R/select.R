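#' Iterative correlation pruning
#'
#' While any surviving pair of features exceeds the threshold in absolute
#' correlation, takes the worst offending pair (largest |r|, ties broken
#' lexicographically by the pair's feature names) and drops the member
#' whose mean absolute correlation with all currently surviving features
#' is higher (ties broken lexicographically, dropping the later name).
#' Constant features have undefined correlations and are dropped first
#' with a warning.
#'
#' @param data Tibble/data frame of numeric feature columns (extra
#'   non-numeric columns such as `subject_id`/`label` are ignored).
#' @param threshold Absolute-correlation threshold (default 0.75).
#' @param method Correlation type, `"pearson"` (default) or
#'   `"spearman"`.
#' @return List: `kept` (character), `dropped` (tibble with `feature`,
#'   `against`, `abs_r` for each removal).
#' @export
prune_correlated <- function(data, threshold = 0.75, method = "pearson") {
  feats <- data[vapply(data, is.numeric, logical(1))]
  feats <- feats[setdiff(names(feats), c("subject_id"))]
  stopifnot(ncol(feats) >= 2, nrow(feats) >= 3)
  dropped <- list()
  const <- names(feats)[vapply(feats, function(x) sd(x) == 0, logical(1))]
  if (length(const)) {
    warning("dropping constant feature(s): ", paste(const, collapse = ", "))
    for (f in const)
      dropped[[length(dropped) + 1]] <-
        tibble::tibble(feature = f, against = NA_character_, abs_r = NA_real_)
    feats <- feats[setdiff(names(feats), const)]
  }
  cm <- abs(cor(as.matrix(feats), method = method))
  alive <- sort(colnames(cm))
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    diag(sub) <- 0
    if (length(alive) < 2 || max(sub) <= threshold) break
    w <- which(sub == max(sub), arr.ind = TRUE)
    pairs <- t(apply(w, 1, function(r) sort(c(rownames(sub)[r[1]],
                                              colnames(sub)[r[2]]))))
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    pair <- pairs[1, ]
    mean_abs <- rowMeans(sub[pair, , drop = FALSE])
    drop <- if (mean_abs[1] > mean_abs[2]) pair[1]
            else if (mean_abs[2] > mean_abs[1]) pair[2]
            else max(pair)
    dropped[[length(dropped) + 1]] <- tibble::tibble(
      feature = drop, against = setdiff(pair, drop), abs_r = max(sub))
    alive <- setdiff(alive, drop)
  }
  list(kept = alive,
       dropped = if (length(dropped)) dplyr::bind_rows(dropped)
                 else tibble::tibble(feature = character(),
                                     against = character(),
                                     abs_r = numeric()))
}

# equal-frequency discretization used by the MI estimator
.ef_bins <- function(x, n_bins) {
  n <- length(x)
  as.integer(ceiling(rank(x, ties.method = "first") * n_bins / n))
}

#' Plug-in mutual information between a feature and a label (or feature)
#'
#' Discretizes numeric variables into `n_bins` equal-frequency bins
#' (default `floor(sqrt(n))` capped at 10; categorical variables are used
#' as-is) and returns the plug-in mutual information of the joint
#' histogram, in nats. Zero if and only if the binned variables are
#' empirically independent.
#'
#' @param x Numeric feature vector.
#' @param y Label (factor/character) or second numeric feature.
#' @param n_bins Number of bins for numeric variables.
#' @return Mutual information in nats (>= 0).
#' @export
mutual_information <- function(x, y, n_bins = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(n_bins)) n_bins <- max(2L, min(10L, floor(sqrt(n))))
  xb <- .ef_bins(x, n_bins)
  yb <- if (is.numeric(y)) .ef_bins(y, n_bins) else as.integer(factor(y))
  if (length(unique(yb)) < 2 && !is.numeric(y))
    stop("invalid cohort: label has a single class")
  joint <- table(xb, yb) / n
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

#' Greedy mRMR feature selection (mutual-information difference)
#'
#' The first pick maximizes relevance MI(feature; label); each later step
#' picks the feature maximizing relevance minus the mean MI with the
#' already-selected features (the MID criterion), with lexicographic
#' tie-breaking. Feature-feature MI uses the same equal-frequency binning
#' as feature-label MI.
#'
#' @param data Tibble of numeric feature columns (plus optional
#'   `subject_id` ignored).
#' @param labels Character/factor vector of class labels.
#' @param k Number of features to select.
#' @param n_bins Bin count forwarded to [mutual_information()].
#' @return Tibble in selection order: `feature`, `relevance`,
#'   `redundancy`, `score`.
#' @export
mrmr_select <- function(data, labels, k = 5, n_bins = NULL) {
  feats <- data[vapply(data, is.numeric, logical(1))]
  feats <- feats[setdiff(names(feats), "subject_id")]
  if (k > ncol(feats))
    stop("selection error: k exceeds the number of available features")
  if (length(unique(labels)) < 2)
    stop("invalid cohort: label has a single class")
  nms <- sort(names(feats))
  rel <- vapply(nms, function(nm)
    mutual_information(feats[[nm]], labels, n_bins = n_bins), numeric(1))
  selected <- character(0)
  rows <- list()
  mi_cache <- matrix(NA_real_, length(nms), length(nms),
                     dimnames = list(nms, nms))
  while (length(selected) < k) {
    cand <- setdiff(nms, selected)
    red <- vapply(cand, function(nm) {
      if (!length(selected)) return(0)
      mean(vapply(selected, function(s) {
        if (is.na(mi_cache[nm, s])) {
          v <- mutual_information(feats[[nm]], feats[[s]], n_bins = n_bins)
          mi_cache[nm, s] <<- v; mi_cache[s, nm] <<- v
        }
        mi_cache[nm, s]
      }, numeric(1)))
    }, numeric(1))
    score <- rel[cand] - red
    best <- cand[which.max(score)]      # cand sorted, so ties -> first name
    rows[[length(rows) + 1]] <- tibble::tibble(
      feature = best, relevance = unname(rel[best]),
      redundancy = unname(red[best]), score = unname(score[best]))
    selected <- c(selected, best)
  }
  dplyr::bind_rows(rows)
}

#' Two-stage feature reduction: correlation pruning then mRMR
#'
#' Convenience wrapper mirroring the screening-to-model reduction:
#' restrict to significant features, prune correlated pairs at the
#' threshold, then rank the survivors by mRMR and keep the top k.
#'
#' @param data Feature tibble (with `label` and optional `subject_id`).
#' @param screen A `ki67_screen` from [screen_features()], or `NULL` to
#'   use all features.
#' @param label_col Label column name.
#' @param threshold Correlation-pruning threshold.
#' @param k Panel size.
#' @return List: `pruning` (from [prune_correlated()]), `ranking` (from
#'   [mrmr_select()]), `panel` (character vector of k features).
#' @export
select_panel <- function(data, screen = NULL, label_col = "label",
                         threshold = 0.75, k = 5) {
  labels <- data[[label_col]]
  feats <- data[setdiff(names(data), c(label_col, "subject_id"))]
  if (!is.null(screen)) {
    sig <- screen$feature[screen$significant]
    feats <- feats[intersect(names(feats), sig)]
  }
  if (ncol(feats) < k)
    stop("selection error: fewer candidate features than k")
  pruning <- prune_correlated(feats, threshold = threshold)
  ranking <- mrmr_select(feats[pruning$kept], labels, k = min(k, length(pruning$kept)))
  list(pruning = pruning, ranking = ranking, panel = ranking$feature)
}
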