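test_that("enhancement ratios and voxel classification follow the rule", {
  expect_equal(enhancement_ratio(100, 160), 0.6)
  expect_equal(enhancement_ratio(160, 160), 0)
  expect_equal(enhancement_ratio(160, 140), -0.125)
  expect_identical(enhancement_ratio(0, 50), -Inf)

  codes <- subregion_levels()
  expect_identical(classify_voxel(100, 160, 180), unname(codes["persistent"]))
  expect_identical(classify_voxel(100, 160, 140), unname(codes["washout"]))
  expect_identical(classify_voxel(100, 160, 165), unname(codes["plateau"]))
  expect_identical(classify_voxel(100, 149, 500),
                   unname(codes["nonenhancing"]))
})

test_that("threshold boundaries are strict: both band edges fall to plateau", {
  # ER_first exactly 0.5 is not enhancing
  expect_identical(classify_voxel(100, 150, 300), 0L)
  expect_identical(classify_voxel(100, 150 + 1e-9, 300), 3L)
  # ER_last exactly +0.1 and -0.1 are plateau
  expect_identical(classify_voxel(100, 160, 160 * 1.1), 2L)
  expect_identical(classify_voxel(100, 160, 160 * 0.9), 2L)
  expect_identical(classify_voxel(100, 160, 160 * 1.1 + 1e-6), 3L)
  expect_identical(classify_voxel(100, 160, 160 * 0.9 - 1e-6), 1L)
})

test_that("subregion maps recover phantom fractions and ignore mid phases", {
  spec <- test_spec(noise_sigma = 0)
  st <- generate_study(spec, "low", seed = 4)
  map <- build_subregion_map(st)
  f <- spec$fractions
  expect_true(all(abs(map$fractions[c("washout", "plateau", "persistent")] -
                        f) <= 0.01))
  # only plain, first and last phases matter
  st_perm <- st
  st_perm$phases <- st$phases[c(1, 2, 6, 4, 5, 3, 7)]
  expect_identical(build_subregion_map(st_perm)$labels, map$labels)

  # a lesion enhancing by exactly 40% everywhere is non-enhancing
  st40 <- st
  st40$phases <- lapply(seq_len(7), function(p) {
    v <- array(100, dim(st$voi))
    if (p > 1) v[st$voi] <- 140
    v
  })
  m40 <- build_subregion_map(st40)
  expect_identical(sum(m40$counts[c("washout", "plateau", "persistent")]),
                   0L)
})

test_that("the partition identity holds and the malignant mask is the union", {
  for (seed in 1:5) {
    st <- random_study(seed)
    map <- build_subregion_map(st)
    expect_identical(sum(map$counts), sum(st$voi))
  }
  spec <- test_spec()
  st <- generate_study(spec, "low", seed = 8)
  map <- build_subregion_map(st)
  mm <- malignant_mask(map)
  expect_identical(sum(mm),
                   unname(map$counts["washout"] + map$counts["plateau"]))
  # all labels 1-3 are inside the VOI
  expect_true(all(st$voi[map$labels >= 1L]))
})

test_that("an all-persistent lesion has no malignant subregion", {
  d <- c(6, 6, 6)
  phases <- lapply(1:7, function(p) {
    v <- array(100, d)
    if (p > 1) v[] <- 180 + (p - 2) * 10    # keeps rising
    v
  })
  st <- structure(list(phases = phases, times = 60 * 0:6,
                       voi = array(TRUE, d), truth = NULL, label = "low",
                       spacing = c(1, 1, 1), subject_id = "x"),
                  class = "dce_study")
  map <- build_subregion_map(st)
  expect_identical(unname(map$counts["persistent"]), as.integer(prod(d)))
  expect_error(malignant_mask(map), "empty malignant subregion")
})

test_that("malignant mask matches ground truth closely under noise", {
  spec <- test_spec(noise_sigma = 4)
  st <- generate_study(spec, "high", seed = 6)
  mm <- malignant_mask(build_subregion_map(st))
  truth_mm <- st$truth == 1L | st$truth == 2L
  dice <- 2 * sum(mm & truth_mm) / (sum(mm) + sum(truth_mm))
  expect_gte(dice, 0.95)
})

test_that("raising the enhancement gate can only shrink the enhancing set", {
  st <- random_study(11)
  plain <- st$phases[[1]][st$voi]
  first <- st$phases[[2]][st$voi]
  er1 <- enhancement_ratio(plain, first)
  for (gate in c(0.5, 0.7, 0.9, 1.2)) {
    enh_lo <- sum(er1 > gate)
    enh_hi <- sum(er1 > gate + 0.2)
    expect_lte(enh_hi, enh_lo)
  }
})

test_that("the map equals a per-voxel nested-conditional oracle", {
  for (seed in 1:25) {
    st <- random_study(seed)
    map <- build_subregion_map(st)
    idx <- which(st$voi)
    eps <- 1e-6 * max(st$phases[[1]][idx])
    oracle <- vapply(idx, function(i)
      oracle_classify_one(st$phases[[1]][i], st$phases[[2]][i],
                          st$phases[[7]][i], eps = eps), integer(1))
    expect_identical(map$labels[idx], oracle)
  }
})

test_that("subregion maps serialize to NIfTI plus JSON", {
  spec <- test_spec(grid = c(16, 16, 12), lesion_semiaxes = c(5, 4, 4))
  st <- generate_study(spec, "low", seed = 2)
  map <- build_subregion_map(st)
  dir <- withr::local_tempdir()
  files <- write_subregion_map(map, dir)
  expect_true(all(file.exists(files)))
  back <- RNifti::readNifti(files[1])
  expect_identical(array(as.integer(back), dim(map$labels)), map$labels)
  js <- jsonlite::read_json(files[2])
  expect_identical(js$counts$washout, unname(as.integer(map$counts["washout"])))
})
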