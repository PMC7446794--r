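# Independent oracles used to freeze expected values. Each is written from
# first principles and never calls the implementation path it checks.

## Exhaustive search for integer confusion matrices consistent with printed
## screening percentages (1-decimal rounding), given the gold-standard
## positive/negative totals. Direct arithmetic only.
solve_confusion <- function(n_pos, n_neg, accuracy, sensitivity, specificity,
                            ppv, npv) {
  hits <- list()
  for (tp in 0:n_pos) for (tn in 0:n_neg) {
    fn <- n_pos - tp; fp <- n_neg - tn
    ok <- function(num, den, target)
      if (den == 0) is.na(target) else round(100 * num / den, 1) == target
    if (ok(tp + tn, n_pos + n_neg, accuracy) &&
        ok(tp, n_pos, sensitivity) && ok(tn, n_neg, specificity) &&
        ok(tp, tp + fp, ppv) && ok(tn, tn + fn, npv))
      hits[[length(hits) + 1L]] <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  }
  hits
}

## Brute-force PCA: eigendecomposition of the sample covariance matrix.
pca_bruteforce <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X))
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  r <- min(nrow(X) - 1L, ncol(X))
  list(loadings = ev$vectors[, seq_len(r), drop = FALSE],
       variance_fraction = ev$values[seq_len(r)] / sum(pmax(ev$values, 0)),
       scores = Xc %*% ev$vectors[, seq_len(r), drop = FALSE])
}

## Closed-form two-class Fisher discriminant on 1-D scores: the decision
## boundary is the midpoint of the class means (equal priors, pooled var).
fisher_threshold_1d <- function(x, labels) {
  classes <- sort(unique(labels))
  mean(c(mean(x[labels == classes[1L]]), mean(x[labels == classes[2L]])))
}

## Permutation test for the one-way ANOVA F statistic.
perm_anova_p <- function(values, groups, n_perm = 10000, seed = 1) {
  f_stat <- function(v, g) {
    gm <- tapply(v, g, mean); n <- tapply(v, g, length)
    ssb <- sum(n * (gm - mean(v))^2); k <- length(gm)
    ssw <- sum((v - gm[g])^2)
    (ssb / (k - 1)) / (ssw / (length(v) - k))
  }
  g <- factor(groups)
  obs <- f_stat(values, g)
  set.seed(seed)
  exceed <- replicate(n_perm, f_stat(sample(values), g) >= obs)
  (sum(exceed) + 1) / (n_perm + 1)
}
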