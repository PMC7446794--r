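#' Peak specification for the synthetic cohort generator
#'
#' @param center Band position, cm^-1.
#' @param width Gaussian sigma, cm^-1 (> 0).
#' @param base_height Peak height in arbitrary units (>= 0).
#' @param class_effect Named numeric vector of multiplicative factors (> 0)
#'   applied per class; classes not named get factor 1.
#' @return A list of class `peak_spec`.
#' @export
peak_spec <- function(center, width, base_height, class_effect = NULL) {
  stopifnot(width > 0, base_height >= 0)
  if (!is.null(class_effect)) {
    stopifnot(!is.null(names(class_effect)), all(class_effect > 0))
  }
  structure(list(center = center, width = width, base_height = base_height,
                 class_effect = class_effect), class = "peak_spec")
}

#' Default urine-like peak set
#'
#' Gaussian bands at the wavenumbers of the urine molecular signature
#' (576, 702, 721, 817, 827, 846, 981, 1004, 1048, 1065, 1127, 1297, 1340,
#' 1417, 1518 cm^-1) plus background urine bands, with moderate default
#' class effects on the disease-associated bands: nucleic-acid and
#' collagen-associated bands elevated and carotenoid bands depressed in the
#' positive class, the pattern a metabolome shift of this kind would show.
#'
#' @param positive_class Label receiving the class effects.
#' @return List of [peak_spec()] objects.
#' @export
default_peak_set <- function(positive_class = "BCA-positive") {
  eff <- function(f) stats::setNames(f, positive_class)
  c(
    ## signature bands (class-shifted in the positive class)
    list(
      peak_spec(576,  9, 1.2, eff(1.25)),   # phosphatidylinositol
      peak_spec(702,  8, 1.0, eff(1.20)),   # cholesterol / fatty acids
      peak_spec(721,  8, 1.5, eff(1.30)),   # nucleic acids
      peak_spec(817,  8, 1.2, eff(1.25)),   # collagen backbone
      peak_spec(827,  8, 1.4, eff(1.30)),   # nucleic acids / tyrosine
      peak_spec(846,  9, 1.0, eff(1.15)),   # monosaccharides
      peak_spec(981,  9, 1.3, eff(1.25)),   # protein beta-sheet
      peak_spec(1004, 6, 2.0, eff(1.20)),   # phenylalanine ring breathing
      peak_spec(1048, 9, 1.1, eff(1.15)),   # glycogen
      peak_spec(1065, 9, 1.2, eff(1.20)),   # collagen / proline
      peak_spec(1127, 9, 1.1, eff(1.20)),   # protein C-N stretch
      peak_spec(1297, 10, 1.0, eff(1.15)),  # fatty acid CH2 twist
      peak_spec(1340, 10, 1.6, eff(1.30)),  # nucleic acids / collagen
      peak_spec(1417, 10, 0.9, eff(0.80)),  # carotenoids
      peak_spec(1518, 10, 0.9, eff(0.80))), # carotenoids
    ## background urine bands, class-neutral (urea dominates real spectra)
    list(
      peak_spec(527,  10, 2.5),
      peak_spec(1001, 7, 8.0),              # urea symmetric stretch
      peak_spec(1161, 12, 2.0),
      peak_spec(1445, 14, 2.2),
      peak_spec(1640, 16, 3.0))
  )
}

#' Synthetic cohort configuration
#'
#' Defines a reproducible synthetic urine Raman cohort emulating the
#' acquisition structure of the clinical studies: a 100-3000 cm^-1 grid at
#' 1 cm^-1 spacing, 17 positive and 39 negative specimens, 10 replicate
#' scans per specimen, smooth per-specimen cubic fluorescence baselines,
#' urine-like Gaussian peak sets whose heights shift by class, log-normal
#' between-specimen height jitter and additive Gaussian scan noise.
#'
#' @param grid Numeric `c(start, stop, step)` in cm^-1.
#' @param n_per_class Named integer vector, class label -> specimen count.
#' @param scans_per_specimen Replicate scans per specimen.
#' @param peaks List of [peak_spec()]; default [default_peak_set()] targeted
#'   at the first class in `n_per_class`.
#' @param baseline_ranges 4 x 2 matrix of uniform sampling ranges for the
#'   cubic baseline coefficients (rows: intercept..cubic, on a unit-scaled
#'   wavenumber axis).
#' @param specimen_sd Log-normal sdlog of between-specimen peak-height
#'   jitter (>= 0).
#' @param scan_sd Additive Gaussian per-scan noise sd, a.u. (>= 0).
#' @param seed Integer seed; mandatory, the generator has no hidden state.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(grid = c(100, 3000, 1),
                             n_per_class = c("BCA-positive" = 17,
                                             "BCA-negative" = 39),
                             scans_per_specimen = 10L,
                             peaks = default_peak_set(names(n_per_class)[1L]),
                             baseline_ranges = rbind(c(20, 60), c(-30, 30),
                                                     c(-20, 20), c(-10, 10)),
                             specimen_sd = 0.15,
                             scan_sd = 0.3,
                             seed) {
  if (missing(seed)) stop("seed is mandatory for synthetic cohorts")
  stopifnot(length(grid) == 3L, grid[2L] > grid[1L], grid[3L] > 0,
            !is.null(names(n_per_class)), all(n_per_class >= 1),
            scans_per_specimen >= 1, specimen_sd >= 0, scan_sd >= 0,
            is.matrix(baseline_ranges), nrow(baseline_ranges) == 4L)
  structure(list(grid = grid, n_per_class = n_per_class,
                 scans_per_specimen = as.integer(scans_per_specimen),
                 peaks = peaks, baseline_ranges = baseline_ranges,
                 specimen_sd = specimen_sd, scan_sd = scan_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

## run expr with its own RNG stream seeded from `seed`, restoring global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic urine Raman cohort with known ground truth
#'
#' Each scan is `baseline(w) + sum_p height_p * class_factor_p *
#' specimen_jitter_p * exp(-(w - center_p)^2 / (2 sigma_p^2)) + noise`.
#' Fully reproducible from the config seed; the ground-truth record retains
#' the per-specimen baseline coefficients and realized peak heights so that
#' baseline-recovery and signature-recovery tests have an external truth.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `set` (a raw `spectrum_set`) and `truth` (list:
#'   `specimens` data.frame with class labels and baseline coefficients,
#'   `peak_heights` specimens x peaks matrix of realized heights,
#'   `peaks` the peak list, `grid_range` for evaluating baselines via
#'   [truth_baseline()]).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    w <- seq(cfg$grid[1L], cfg$grid[2L], by = cfg$grid[3L])
    t01 <- (w - w[1L]) / (w[length(w)] - w[1L])
    Tm <- outer(t01, 0:3, `^`)
    classes <- rep(names(cfg$n_per_class), cfg$n_per_class)
    n_spec <- length(classes)
    ids <- sprintf("%s-%02d", classes, unlist(lapply(cfg$n_per_class, seq_len)))
    n_pk <- length(cfg$peaks)

    ## peak profile matrix (wavenumbers x peaks), fixed across specimens
    P <- vapply(cfg$peaks, function(p)
      exp(-(w - p$center)^2 / (2 * p$width^2)), numeric(length(w)))
    base_h <- vapply(cfg$peaks, `[[`, 0, "base_height")
    factor_for <- function(p, cl) {
      f <- p$class_effect
      if (!is.null(f) && cl %in% names(f)) unname(f[cl]) else 1
    }

    bl_coef <- matrix(0, n_spec, 4L)
    heights <- matrix(0, n_spec, n_pk)
    rows <- vector("list", n_spec * cfg$scans_per_specimen)
    row_ids <- character(length(rows)); row_scans <- integer(length(rows))
    r <- 0L
    for (i in seq_len(n_spec)) {
      bl_coef[i, ] <- stats::runif(4L, cfg$baseline_ranges[, 1L],
                                   cfg$baseline_ranges[, 2L])
      jitter <- exp(stats::rnorm(n_pk, 0, cfg$specimen_sd))
      heights[i, ] <- base_h * jitter *
        vapply(cfg$peaks, factor_for, 0, cl = classes[i])
      clean <- drop(Tm %*% bl_coef[i, ]) + drop(P %*% heights[i, ])
      for (s in seq_len(cfg$scans_per_specimen)) {
        r <- r + 1L
        rows[[r]] <- clean + stats::rnorm(length(w), 0, cfg$scan_sd)
        row_ids[r] <- ids[i]
        row_scans[r] <- s - 1L
      }
    }
    md <- data.frame(specimen_id = ids, class_label = classes,
                     dataset = "synthetic", sex = NA_character_,
                     age = NA_real_, stringsAsFactors = FALSE)
    set <- new_spectrum_set(w, do.call(rbind, rows), row_ids, row_scans, md)
    truth <- list(
      specimens = data.frame(specimen_id = ids, class_label = classes,
                             b0 = bl_coef[, 1L], b1 = bl_coef[, 2L],
                             b2 = bl_coef[, 3L], b3 = bl_coef[, 4L],
                             stringsAsFactors = FALSE),
      peak_heights = heights,
      peaks = cfg$peaks,
      grid_range = range(w))
    list(set = set, truth = truth)
  })
}

#' Evaluate a cohort's ground-truth baseline on a wavenumber grid
#'
#' @param truth The `truth` record returned by [generate_cohort()].
#' @param specimen_id Specimen whose baseline to evaluate.
#' @param wavenumbers Grid to evaluate on (typically the truncated grid).
#' @return Numeric baseline vector.
#' @export
truth_baseline <- function(truth, specimen_id, wavenumbers) {
  i <- match(specimen_id, truth$specimens$specimen_id)
  if (is.na(i)) stop("unknown specimen: ", specimen_id)
  t01 <- (wavenumbers - truth$grid_range[1L]) /
    (truth$grid_range[2L] - truth$grid_range[1L])
  drop(outer(t01, 0:3, `^`) %*%
         as.numeric(truth$specimens[i, c("b0", "b1", "b2", "b3")]))
}

#' Generate a null cohort (no class effect)
#'
#' Identical to [generate_cohort()] but with every peak's class-effect
#' factor forced to 1, keeping the class labels: class mean spectra then
#' differ only by sampling noise, the null against which chance-level
#' screening behavior is measured.
#'
#' @param cfg A [synthetic_config()].
#' @return A raw `spectrum_set` (labels retained, no class signal).
#' @export
null_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cfg$peaks <- lapply(cfg$peaks, function(p) { p$class_effect <- NULL; p })
  generate_cohort(cfg)$set
}
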