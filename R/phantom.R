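#' Phantom cohort specification
#'
#' Collects every parameter of the synthetic DCE-MRI generator: grid
#' geometry, lesion ellipsoid, kinetic subregion volume fractions, noise
#' level, the spatial-coherence length of the subregion assignment, the
#' intensity-texture field, and the label effect (what distinguishes a
#' "high" Ki-67 study from a "low" one).
#'
#' The label effect has two arms, mirroring the kinds of features a
#' malignant-subregion texture model retains: `effect_corr_mult`
#' multiplies the correlation length of the intensity-texture random field
#' inside the lesion (driving co-occurrence homogeneity/complexity
#' features), and `effect_elong` multiplies the left-right lesion
#' semi-axis (driving the coronal-plane maximum diameter). Effect factors
#' of 1 make the two labels exchangeable (a null generator).
#'
#' @param grid Grid shape in voxels, length 3 (x, y, z).
#' @param spacing Voxel spacing in mm, length 3.
#' @param baseline Pre-contrast signal level (arbitrary units).
#' @param noise_sigma Additive Gaussian noise SD (same units as baseline).
#' @param lesion_center Lesion center in mm, or `NULL` for the grid center.
#' @param lesion_semiaxes Ellipsoid semi-axes in mm (x, y, z).
#' @param fractions Named target volume fractions of the lesion for
#'   washout, plateau and persistent voxels; remainder is non-enhancing.
#' @param coherence_mm Smoothing length of the subregion assignment field.
#' @param texture_corr_mm Correlation length of the intensity texture.
#' @param texture_strength Relative amplitude modulation of the texture.
#' @param effect_corr_mult,effect_elong Label-effect multipliers (high).
#' @param n_high,n_low Cohort sizes per label.
#' @param seed Master seed for [generate_cohort()].
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid = c(64, 64, 48),
                         spacing = c(1, 1, 1.2),
                         baseline = 200,
                         noise_sigma = 2,
                         lesion_center = NULL,
                         lesion_semiaxes = c(12, 10, 10),
                         fractions = c(washout = 0.35, plateau = 0.30,
                                       persistent = 0.20),
                         coherence_mm = 4,
                         texture_corr_mm = 3,
                         texture_strength = 0.25,
                         effect_corr_mult = 2,
                         effect_elong = 1.25,
                         n_high = 81, n_low = 38,
                         seed = 1) {
  fractions <- fractions[c("washout", "plateau", "persistent")]
  stopifnot(length(grid) == 3, length(spacing) == 3, all(spacing > 0),
            all(fractions >= 0), sum(fractions) <= 1,
            n_high >= 1, n_low >= 1, baseline > 0, noise_sigma >= 0)
  if (is.null(lesion_center)) lesion_center <- (grid - 1) * spacing / 2
  extent <- (grid - 1) * spacing
  if (any(lesion_center - lesion_semiaxes < 0) ||
      any(lesion_center + lesion_semiaxes > extent))
    stop("geometry error: lesion ellipsoid does not fit inside the grid")
  structure(list(
    grid = as.integer(grid), spacing = spacing, baseline = baseline,
    noise_sigma = noise_sigma, lesion_center = lesion_center,
    lesion_semiaxes = lesion_semiaxes, fractions = fractions,
    coherence_mm = coherence_mm, texture_corr_mm = texture_corr_mm,
    texture_strength = texture_strength,
    effect_corr_mult = effect_corr_mult, effect_elong = effect_elong,
    n_high = as.integer(n_high), n_low = as.integer(n_low),
    seed = as.integer(seed)), class = "phantom_spec")
}

#' Time-intensity curve template for a kinetic archetype
#'
#' Noise-free per-phase signal multipliers for one enhancement archetype:
#' a rise to `1 + amplitude` at the first post-contrast phase followed by
#' a linear course to a last-phase value set by the late enhancement ratio
#' `er_last`. Only the two enhancement ratios matter to the subregion
#' classifier, so the curve shape is deliberately piecewise linear rather
#' than pharmacokinetic.
#'
#' Class defaults keep every template inside its defining inequalities
#' with a comfortable margin: enhancing archetypes require
#' `amplitude > 0.52` and `er_last` at least 0.02 beyond its threshold.
#'
#' @param archetype One of `"washout"`, `"plateau"`, `"persistent"`,
#'   `"nonenhancing"`.
#' @param times Phase times in seconds, first entry the pre-contrast scan.
#' @param amplitude First-phase enhancement ratio; `NULL` for the class
#'   default (0.8 enhancing, 0.3 non-enhancing).
#' @param er_last Late enhancement ratio (last vs first phase); `NULL`
#'   for the class default (-0.2 washout, 0 plateau, 0.25 persistent,
#'   0.05 non-enhancing).
#' @return Numeric vector of multipliers, one per phase, first entry 1.
#' @export
tic_template <- function(archetype,
                         times = c(0, 60, 120, 180, 240, 300, 360),
                         amplitude = NULL, er_last = NULL) {
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly ascending")
  defaults <- list(
    washout = c(a = 0.8, e = -0.2),
    plateau = c(a = 0.8, e = 0),
    persistent = c(a = 0.8, e = 0.25),
    nonenhancing = c(a = 0.3, e = 0.05))
  if (!archetype %in% names(defaults))
    stop("invalid archetype: ", archetype)
  d <- defaults[[archetype]]
  a <- if (is.null(amplitude)) d[["a"]] else amplitude
  e <- if (is.null(er_last)) d[["e"]] else er_last
  if (archetype == "nonenhancing") {
    if (a > 0.48) stop("nonenhancing amplitude must be <= 0.48")
  } else if (a < 0.52) {
    stop("enhancing amplitude must be >= 0.52")
  }
  lim <- switch(archetype,
    washout = e <= -0.12,
    plateau = abs(e) <= 0.08,
    persistent = e >= 0.12,
    nonenhancing = TRUE)
  if (!lim) stop("er_last violates the archetype inequality margin")
  n <- length(times)
  m <- numeric(n)
  m[1] <- 1
  frac <- (times[-1] - times[2]) / (times[n] - times[2])
  m[-1] <- (1 + a) * (1 + e * frac)
  if (any(m < 0)) stop("negative multiplier; lower |er_last| or amplitude")
  m
}

# Gaussian random field: white noise smoothed by a separable Gaussian of
# physical length sigma_mm, then standardized inside `within` (or globally).
.gaussian_field <- function(grid, spacing, sigma_mm, within = NULL) {
  g <- array(rnorm(prod(grid)), dim = grid)
  for (ax in 1:3) {
    s <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    n <- grid[ax]
    W <- matrix(0, n, n)
    for (j in seq_along(k)) {
      idx <- pmin(pmax(seq_len(n) + (j - r - 1L), 1L), n)
      W[cbind(seq_len(n), idx)] <- W[cbind(seq_len(n), idx)] + k[j]
    }
    g <- .apply_axis(g, W, ax)
  }
  v <- if (is.null(within)) g else g[within]
  (g - mean(v)) / sd(as.vector(v))
}

#' Generate one synthetic DCE-MRI study
#'
#' Builds a 7-phase study (pre-contrast plus post-contrast phases at 60 to
#' 360 s) containing one ellipsoidal lesion. Lesion voxels are partitioned
#' into the four kinetic archetypes by rank-thresholding a Gaussian random
#' field smoothed at the spec's coherence length, so the empirical class
#' fractions match the requested ones exactly while remaining spatially
#' contiguous. Each voxel follows its archetype's [tic_template()], with
#' the first-phase amplitude modulated by a second, textural random field;
#' for label `"high"` that field's correlation length and the lesion's
#' left-right semi-axis are multiplied by the spec's effect factors.
#' Additive Gaussian noise is applied to every phase.
#'
#' @param spec A [phantom_spec()].
#' @param label `"high"` or `"low"`.
#' @param seed Integer seed; identical `(spec, label, seed)` give
#'   bit-identical studies.
#' @return A `dce_study`: list with `phases` (list of 7 arrays), `times`,
#'   `voi` (logical array), `truth` (a `subregion_map`-style integer array,
#'   -1 outside the VOI), `label`, `spacing`, `subject_id`.
#' @export
generate_study <- function(spec, label = c("low", "high"), seed = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  label <- match.arg(label)
  set.seed(seed)
  grid <- spec$grid; spacing <- spec$spacing
  semi <- spec$lesion_semiaxes
  if (label == "high") semi[1] <- semi[1] * spec$effect_elong
  extent <- (grid - 1) * spacing
  if (any(spec$lesion_center - semi < 0) ||
      any(spec$lesion_center + semi > extent))
    stop("geometry error: lesion (after elongation) exceeds the grid")

  cx <- (seq_len(grid[1]) - 1) * spacing[1]
  cy <- (seq_len(grid[2]) - 1) * spacing[2]
  cz <- (seq_len(grid[3]) - 1) * spacing[3]
  dx2 <- ((cx - spec$lesion_center[1]) / semi[1])^2
  dy2 <- ((cy - spec$lesion_center[2]) / semi[2])^2
  dz2 <- ((cz - spec$lesion_center[3]) / semi[3])^2
  voi <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  if (!any(voi)) stop("geometry error: empty lesion")
  idx <- which(voi)

  # spatially coherent archetype assignment with exact fractions
  u <- .gaussian_field(grid, spacing, spec$coherence_mm, within = voi)
  r <- rank(u[idx], ties.method = "first") / length(idx)
  f <- cumsum(spec$fractions)
  cls <- integer(length(idx))                 # 0 non-enhancing
  cls[r <= f[1]] <- 1L                        # washout
  cls[r > f[1] & r <= f[2]] <- 2L             # plateau
  cls[r > f[2] & r <= f[3]] <- 3L             # persistent
  truth <- array(-1L, dim = grid)
  truth[idx] <- cls

  # textural amplitude modulation; correlation length carries the effect
  corr_mm <- spec$texture_corr_mm *
    if (label == "high") spec$effect_corr_mult else 1
  tex <- .gaussian_field(grid, spacing, corr_mm, within = voi)
  tex <- pmin(pmax(tex[idx], -2), 2)
  amp <- ifelse(cls == 0L, 0.3, 0.8) * (1 + spec$texture_strength * tex)
  amp <- ifelse(cls == 0L, pmin(amp, 0.45), pmax(amp, 0.55))
  er_last <- c(0.05, -0.2, 0, 0.25)[cls + 1L]

  times <- c(0, 60, 120, 180, 240, 300, 360)
  n_ph <- length(times)
  frac <- c(0, (times[-1] - times[2]) / (times[n_ph] - times[2]))
  phases <- vector("list", n_ph)
  for (p in seq_len(n_ph)) {
    vol <- array(spec$baseline, dim = grid)
    mult <- if (p == 1) rep(1, length(idx))
            else (1 + amp) * (1 + er_last * frac[p])
    vol[idx] <- spec$baseline * mult
    if (spec$noise_sigma > 0)
      vol <- vol + array(rnorm(prod(grid), sd = spec$noise_sigma), dim = grid)
    phases[[p]] <- vol
  }
  structure(list(phases = phases, times = times, voi = voi, truth = truth,
                 label = label, spacing = spacing, subject_id = NA_character_),
            class = "dce_study")
}

#' Generate a phantom cohort
#'
#' Draws `n_high + n_low` studies with per-study seeds derived
#' deterministically from the spec's master seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `studies` (list of `dce_study`) and `cohort`, a tibble
#'   with columns `subject_id` and `label`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_high + spec$n_low
  set.seed(spec$seed)
  study_seeds <- sample.int(.Machine$integer.max - 1L, n)
  labels <- c(rep("high", spec$n_high), rep("low", spec$n_low))
  ids <- sprintf("sub-%03d", seq_len(n))
  studies <- vector("list", n)
  for (i in seq_len(n)) {
    st <- generate_study(spec, label = labels[i], seed = study_seeds[i])
    st$subject_id <- ids[i]
    studies[[i]] <- st
  }
  list(studies = studies,
       cohort = tibble::tibble(subject_id = ids, label = labels))
}

#' @export
print.dce_study <- function(x, ...) {
  cat("DCE study", if (!is.na(x$subject_id)) x$subject_id else "",
      ":", length(x$phases), "phases,",
      paste(dim(x$voi), collapse = "x"), "grid,",
      sum(x$voi), "VOI voxels, label", x$label, "\n")
  invisible(x)
}

#' Read a phantom specification from YAML
#'
#' The YAML keys mirror the arguments of [phantom_spec()]; absent keys
#' take the defaults.
#'
#' @param path YAML file path.
#' @return A `phantom_spec`.
#' @export
phantom_spec_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(phantom_spec))
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown phantom config key(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(cfg$fractions)) cfg$fractions <- unlist(cfg$fractions)
  do.call(phantom_spec, cfg)
}
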