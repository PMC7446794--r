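#' Total principal component distance (TPD)
#'
#' Reduces each spectrum to a single scalar: the distance between its top
#' four PC scores and those of a reference spectrum (by convention the
#' synthetic urinalysis control, or the time-zero measurement in stability
#' studies). Two variants are exposed because the published formula's
#' exponent placement is typographically ambiguous:
#' `abs_sum`, the default, is `sum_i |P_u,i - P_ref,i|` over i = 1..4;
#' `sq_sum` is `sum_i (P_u,i - P_ref,i)^2`. The PCA is conventionally fitted
#' on unaveraged replicate scans; when the reference specimen has several
#' scans its mean score vector is used.
#'
#' @param pca A fitted [fit_pca()] model with >= 4 components.
#' @param set The `spectrum_set` scored against the model (typically the
#'   unaveraged preprocessed set the model was fitted on).
#' @param reference_id Specimen id of the reference; all its scans are
#'   averaged in score space.
#' @param variant `"abs_sum"` or `"sq_sum"`.
#' @param n_pcs Number of leading components in the distance (default 4).
#' @return A data.frame of class `tpd_result` with columns `specimen_id`,
#'   `scan_index`, `tpd`; attributes `reference_id`, `variant`, `n_pcs_used`.
#' @export
compute_tpd <- function(pca, set, reference_id,
                        variant = c("abs_sum", "sq_sum"), n_pcs = 4L) {
  variant <- match.arg(variant)
  if (pca$n_components < n_pcs)
    stop("PCA model has fewer than ", n_pcs, " components")
  if (!reference_id %in% set$specimen_ids)
    stop("reference specimen not present: ", reference_id)
  S <- project(pca, set, n_pcs)
  ref <- colMeans(S[set$specimen_ids == reference_id, , drop = FALSE])
  D <- sweep(S, 2L, ref)
  tpd <- if (variant == "abs_sum") rowSums(abs(D)) else rowSums(D^2)
  out <- data.frame(specimen_id = set$specimen_ids,
                    scan_index = set$scan_indices, tpd = tpd,
                    stringsAsFactors = FALSE)
  attr(out, "reference_id") <- reference_id
  attr(out, "variant") <- variant
  attr(out, "n_pcs_used") <- as.integer(n_pcs)
  class(out) <- c("tpd_result", "data.frame")
  out
}

tpd_groups <- function(tpd, groups) {
  if (length(groups) != nrow(tpd))
    stop("groups must have one label per TPD row")
  g <- factor(groups)
  sizes <- table(g)
  if (nlevels(g) < 2L) stop("need >= 2 groups")
  if (any(sizes < 2L))
    stop("every group needs >= 2 members; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  g
}

#' One-way ANOVA on TPD values
#'
#' Classical fixed-effects one-way analysis of variance of the TPD scalar
#' across labelled groups (e.g. disease classes, or storage weeks in a
#' stability study).
#'
#' @param tpd A [compute_tpd()] result.
#' @param groups Per-row group labels (from metadata, same order as `tpd`).
#' @return List with `F`, `p`, `df` and the underlying `stats::aov` fit.
#' @export
anova_tpd <- function(tpd, groups) {
  g <- tpd_groups(tpd, groups)
  fit <- stats::aov(tpd$tpd ~ g)
  tab <- summary(fit)[[1L]]
  Fv <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  if (degenerate_scatter(tpd$tpd, g)["between"]) { Fv <- 0; p <- 1 }
  else if (is.nan(Fv)) { Fv <- 0; p <- 1 }
  list(F = Fv, p = p, df = c(tab[["Df"]][1L], tab[["Df"]][2L]), fit = fit)
}

## scale-aware detection of zero between-/within-group scatter (constant
## values produce rounding-noise sums of squares, not exact zeros)
degenerate_scatter <- function(values, g) {
  eps <- (1e-10 * (max(abs(values)) + 1e-300))^2
  gm <- tapply(values, g, mean)
  n <- tapply(values, g, length)
  ssb <- sum(n * (gm - mean(values))^2)
  ssw <- sum((values - gm[g])^2)
  c(between = ssb <= eps * length(values),
    within = ssw <= eps * length(values))
}

#' Tukey HSD pairwise comparisons of TPD values
#'
#' All unordered group pairs, with family-wise p-values from the studentized
#' range distribution.
#'
#' @inheritParams anova_tpd
#' @return A data.frame with columns `group_a`, `group_b`,
#'   `mean_difference` (TPD units, b minus a) and `p_value`.
#' @export
tukey_pairwise <- function(tpd, groups) {
  g <- tpd_groups(tpd, groups)
  fit <- stats::aov(tpd$tpd ~ g)
  if (degenerate_scatter(tpd$tpd, g)["within"]) {  # identical within groups
    lev <- levels(g)
    pairs <- utils::combn(lev, 2L)
    means <- tapply(tpd$tpd, g, mean)
    diffs <- as.numeric(means[pairs[2L, ]] - means[pairs[1L, ]])
    tol <- 1e-10 * (max(abs(tpd$tpd)) + 1e-300)
    diffs[abs(diffs) <= tol] <- 0
    return(data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                      mean_difference = diffs,
                      p_value = as.numeric(diffs == 0),
                      stringsAsFactors = FALSE))
  }
  th <- stats::TukeyHSD(fit)$g
  nm <- strsplit(rownames(th), "-", fixed = TRUE)
  data.frame(group_a = vapply(nm, `[`, "", 2L),
             group_b = vapply(nm, `[`, "", 1L),
             mean_difference = th[, "diff"],
             p_value = th[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}
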