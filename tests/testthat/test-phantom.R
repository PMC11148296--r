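test_that("TIC templates respect their defining enhancement-ratio bands", {
  times <- c(0, 60, 120, 180, 240, 300, 360)

  m <- tic_template("washout", times, amplitude = 0.6)
  expect_equal(m[1], 1)
  expect_equal(m[2], 1.6)
  expect_lte(m[7], 1.6 * 0.9)

  m <- tic_template("nonenhancing", times)
  expect_true(all(m >= 0.98 & m <= 1.5))
  expect_lte((m[2] - m[1]) / m[1], 0.5)

  expect_error(tic_template("ringlike", times), "invalid archetype")
  expect_error(tic_template("washout", times, amplitude = 0.3), "amplitude")
})

test_that("noise-free templates classify to their own archetype", {
  times <- c(0, 60, 120, 180, 240, 300, 360)
  # plateau: exhaustive amplitude x slope grid
  for (a in seq(0.55, 2, length.out = 10))
    for (e in seq(-0.08, 0.08, length.out = 10)) {
      m <- tic_template("plateau", times, amplitude = a, er_last = e)
      expect_identical(classify_voxel(m[1], m[2], m[7]), 2L)
    }
  # archetype fidelity over random draws per class
  set.seed(42)
  n <- 2500
  draws <- list(
    washout = cbind(runif(n, 0.55, 2), runif(n, -0.6, -0.12)),
    plateau = cbind(runif(n, 0.55, 2), runif(n, -0.08, 0.08)),
    persistent = cbind(runif(n, 0.55, 2), runif(n, 0.12, 0.6)),
    nonenhancing = cbind(runif(n, 0.02, 0.48), runif(n, 0, 0.05)))
  codes <- subregion_levels()
  for (cls in names(draws)) {
    labs <- vapply(seq_len(n), function(i) {
      m <- tic_template(cls, times, amplitude = draws[[cls]][i, 1],
                        er_last = draws[[cls]][i, 2])
      classify_voxel(m[1], m[2], m[7])
    }, integer(1))
    expect_identical(unique(labs), unname(codes[cls]))
  }
})

test_that("generated studies honor fractions, geometry and determinism", {
  spec <- test_spec(noise_sigma = 0)
  st <- generate_study(spec, "low", seed = 5)
  expect_length(st$phases, 7)
  expect_true(all(diff(st$times) > 0))
  idx <- which(st$voi)
  expect_gt(length(idx), 1000)
  emp <- vapply(1:3, function(k) mean(st$truth[idx] == k), numeric(1))
  expect_true(all(abs(emp - spec$fractions) <= 0.05))

  # noise-free ground truth agrees with the kinetic classifier
  map <- build_subregion_map(st)
  expect_gte(mean(map$labels[idx] == st$truth[idx]), 0.99)

  st2 <- generate_study(spec, "low", seed = 5)
  expect_identical(st, st2)

  expect_error(
    generate_study(phantom_spec(grid = c(16, 16, 12),
                                lesion_semiaxes = c(20, 5, 5)),
                   "low", seed = 1),
    "geometry")
})

test_that("noise at 2% of baseline flips few voxel classes", {
  spec <- test_spec(noise_sigma = 4)   # baseline 200
  st <- generate_study(spec, "low", seed = 9)
  idx <- which(st$voi)
  map <- build_subregion_map(st)
  expect_gte(mean(map$labels[idx] == st$truth[idx]), 0.95)
})

test_that("the high label elongates the lesion and lengthens texture", {
  spec <- test_spec(noise_sigma = 0)
  lo <- generate_study(spec, "low", seed = 3)
  hi <- generate_study(spec, "high", seed = 3)
  ext <- function(st) {
    w <- which(st$voi, arr.ind = TRUE)
    diff(range(w[, 1]))
  }
  expect_gt(ext(hi), ext(lo))
})

test_that("cohorts have the requested size, labels and determinism", {
  spec <- test_spec(n_high = 81, n_low = 38, seed = 2,
                    grid = c(16, 16, 12), lesion_semiaxes = c(5, 4, 4))
  co <- generate_cohort(spec)
  expect_length(co$studies, 119)
  expect_equal(nrow(co$cohort), 119)
  expect_equal(sum(co$cohort$label == "high"), 81)
  expect_identical(co$cohort$label,
                   vapply(co$studies, function(s) s$label, character(1)))

  spec2 <- test_spec(n_high = 1, n_low = 1, seed = 7)
  co2 <- generate_cohort(spec2)
  expect_setequal(co2$cohort$label, c("high", "low"))
  co3 <- generate_cohort(spec2)
  expect_identical(co2$studies, co3$studies)
})

test_that("phantom specs validate and load from YAML", {
  expect_error(phantom_spec(fractions = c(washout = 0.6, plateau = 0.5,
                                          persistent = 0.2)),
               "sum")
  expect_error(phantom_spec(n_high = 0), "n_high")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("grid: [16, 16, 12]",
               "lesion_semiaxes: [5, 4, 4]",
               "n_high: 3", "n_low: 2", "seed: 4"), path)
  spec <- phantom_spec_from_yaml(path)
  expect_identical(spec$grid, c(16L, 16L, 12L))
  expect_identical(spec$n_high, 3L)
  writeLines("lesion_radius: 5", path)
  expect_error(phantom_spec_from_yaml(path), "unknown phantom config")
})
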