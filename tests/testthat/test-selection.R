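test_that("correlation pruning drops the more redundant member of a pair", {
  set.seed(21)
  z <- rnorm(50); f3 <- rnorm(50)
  f1 <- 0.9 * z + 0.35 * f3                 # f1 leans more on f3 than f2 does
  f2 <- 0.9 * z + 0.10 * f3 + rnorm(50, sd = 0.05)
  df <- tibble::tibble(f1 = f1, f2 = f2, f3 = f3)
  stopifnot(abs(cor(f1, f2)) > 0.75, abs(cor(f1, f3)) < 0.75)
  res <- prune_correlated(df)
  expect_setequal(res$kept, c("f2", "f3"))
  expect_identical(res$dropped$feature, "f1")

  # all below threshold: identity
  set.seed(22)
  ind <- tibble::as_tibble(as.data.frame(matrix(rnorm(300), 100)))
  res2 <- prune_correlated(ind)
  expect_setequal(res2$kept, names(ind))
  expect_equal(nrow(res2$dropped), 0)

  # idempotence
  rerun <- prune_correlated(ind[res2$kept])
  expect_identical(sort(rerun$kept), sort(res2$kept))

  # constant features go first, with a warning
  expect_warning(res3 <- prune_correlated(dplyr::mutate(ind, cst = 1)),
                 "constant")
  expect_false("cst" %in% res3$kept)
})

test_that("no surviving pair exceeds the threshold after pruning", {
  set.seed(23)
  base <- matrix(rnorm(60 * 4), 60)
  noisy <- base[, sample(4, 20, replace = TRUE)] + matrix(rnorm(60 * 20, sd = 0.3), 60)
  df <- tibble::as_tibble(as.data.frame(noisy))
  res <- prune_correlated(df, threshold = 0.75)
  cm <- abs(cor(as.matrix(df[res$kept])))
  diag(cm) <- 0
  expect_lte(max(cm), 0.75)
})

test_that("mutual information matches theory and a brute-force oracle", {
  lab <- rep(c("high", "low"), each = 50)
  x <- as.numeric(lab == "high") # numeric copy of a balanced label
  expect_equal(mutual_information(x, lab, n_bins = 2), log(2),
               tolerance = 1e-9)

  set.seed(24)
  xi <- rnorm(1e4)
  li <- sample(rep(c("high", "low"), each = 5e3))
  expect_lte(mutual_information(xi, li), 0.01)

  for (i in 1:5) {
    xr <- rnorm(40)
    yr <- rnorm(40)
    nb <- 5
    mi <- mutual_information(xr, yr, n_bins = nb)
    xb <- as.integer(ceiling(rank(xr, ties.method = "first") * nb / 40))
    yb <- as.integer(ceiling(rank(yr, ties.method = "first") * nb / 40))
    expect_equal(mi, oracle_mi(xb, yb), tolerance = 1e-12)
    expect_gte(mi, 0)
  }
})

test_that("mRMR ranks relevance first and penalizes duplicates", {
  set.seed(25)
  lab <- rep(c("high", "low"), each = 30)
  f1 <- as.numeric(lab == "high") + rnorm(60, sd = 0.01)
  df <- tibble::tibble(f1 = f1, f2 = f1, f3 = rnorm(60))
  sel <- mrmr_select(df, lab, k = 2)
  expect_identical(sel$feature, c("f1", "f3"))  # the duplicate loses

  sel1 <- mrmr_select(df, lab, k = 1)
  expect_identical(sel1$feature, "f1")
  expect_equal(sel1$redundancy, 0)

  # adding an exact duplicate of a selected feature never changes the rest
  df4 <- dplyr::mutate(df, f1_copy = f1)
  sel4 <- mrmr_select(df4, lab, k = 3)
  expect_identical(setdiff(sel4$feature, c("f1", "f1_copy"))[1], "f3")

  expect_error(mrmr_select(df, lab, k = 9), "selection error")
  expect_error(mrmr_select(df, rep("high", 60), k = 1), "invalid cohort")
})

test_that("selection is invariant to subject order", {
  set.seed(26)
  lab <- rep(c("high", "low"), times = c(20, 15))
  df <- tibble::as_tibble(as.data.frame(matrix(rnorm(35 * 8), 35)))
  sel <- mrmr_select(df, lab, k = 3)
  perm <- sample(35)
  sel_p <- mrmr_select(df[perm, ], lab[perm], k = 3)
  expect_identical(sel$feature, sel_p$feature)
  pr <- prune_correlated(df, threshold = 0.3)
  pr_p <- prune_correlated(df[perm, ], threshold = 0.3)
  expect_identical(pr$kept, pr_p$kept)
})

test_that("a 47-member correlated block plus 4 independents reduces 51 to 5", {
  set.seed(27)
  n <- 119
  core <- rnorm(n)
  block <- vapply(1:47, function(i) core + rnorm(n, sd = 0.25),
                  numeric(n))
  indep <- matrix(rnorm(n * 4), n)
  df <- tibble::as_tibble(as.data.frame(cbind(block, indep)))
  names(df) <- sprintf("f%02d", 1:51)
  lab <- rep(c("high", "low"), times = c(81, 38))
  pr <- prune_correlated(df, threshold = 0.75)
  expect_identical(nrow(pr$dropped), 46L)
  expect_length(pr$kept, 5)
  sel <- mrmr_select(df[pr$kept], lab, k = 5)
  expect_length(sel$feature, 5)
})

test_that("engineered label-linked features are recovered in the top 5", {
  set.seed(28)
  hits <- vapply(1:100, function(rep) {
    n <- 119
    lab <- rep(c("high", "low"), times = c(81, 38))
    y <- as.numeric(lab == "high")
    linked <- vapply(1:3, function(i) y * 1.5 + rnorm(n), numeric(n))
    noise <- matrix(rnorm(n * 40), n)
    df <- tibble::as_tibble(as.data.frame(cbind(linked, noise)))
    names(df) <- sprintf("f%02d", 1:43)
    sel <- mrmr_select(df, lab, k = 5)
    all(c("f01", "f02", "f03") %in% sel$feature)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
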