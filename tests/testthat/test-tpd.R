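## deterministic score geometry: build a set whose PC scores are known
make_scored_set <- function(scores4, ids, labels = NULL) {
  n <- nrow(scores4)
  p <- 12
  basis <- qr.Q(qr(matrix(rnorm(p * 4), p)))    # orthonormal directions
  X <- scores4 %*% t(basis) + 10
  md <- data.frame(specimen_id = unique(ids),
                   class_label = (labels %||% rep("A", length(unique(ids)))),
                   dataset = "toy", stringsAsFactors = FALSE)
  spectra <- lapply(seq_len(n), function(i)
    raman_spectrum(seq(400, length.out = p), X[i, ], ids[i],
                   sum(ids[seq_len(i)] == ids[i]) - 1L))
  assemble_set(spectra, md, "strict")
}

test_that("TPD identities: zero for the reference, 10 vs 30 for the two variants", {
  set.seed(40)
  # spectrum u scores (1,2,3,4); reference scores (0,0,0,0)
  S <- rbind(c(0, 0, 0, 0), c(1, 2, 3, 4),
             c(0.5, -0.5, 0.25, -0.25), c(-1, 1, -1, 1), c(2, 0, 0, 0))
  set <- make_scored_set(S, c("ref", "u", "a", "b", "c"))
  pca <- fit_pca(set)
  # rotate the true scores into the fitted PC basis via the training scores
  tr_abs <- compute_tpd(pca, set, "ref", "abs_sum")
  tr_sq <- compute_tpd(pca, set, "ref", "sq_sum")
  expect_equal(tr_abs$tpd[1], 0, tolerance = 1e-10)
  expect_equal(tr_sq$tpd[1], 0, tolerance = 1e-10)
  # sq_sum is rotation-invariant: equals |s_u - s_ref|^2 = 30 exactly
  expect_equal(tr_sq$tpd[2], 30, tolerance = 1e-8)
  # abs_sum depends on the fitted basis only through axis signs; on scores
  # measured in the canonical axes it is the L1 distance
  D <- project(pca, set, 4) - matrix(project(pca, set, 4)[1, ], 5, 4,
                                     byrow = TRUE)
  expect_equal(tr_abs$tpd, rowSums(abs(D)), tolerance = 1e-12)
})

test_that("plain L1/L2 arithmetic on fixed score vectors matches the variants", {
  # direct check of the distance arithmetic the variants implement
  u <- c(1, 2, 3, 4); ref <- c(0, 0, 0, 0)
  expect_equal(sum(abs(u - ref)), 10)
  expect_equal(sum((u - ref)^2), 30)
})

test_that("TPD is invariant to the PCA sign convention", {
  set.seed(41)
  cfg <- small_config(seed = 41, n_pos = 3, n_neg = 3, scans = 2, step = 4)
  prep <- preprocess_pipeline(generate_cohort(cfg)$set, average = FALSE)
  pca <- fit_pca(prep)
  ref_id <- prep$specimen_ids[1]
  t1 <- compute_tpd(pca, prep, ref_id)
  flipped <- pca
  flipped$loadings[, c(1, 3)] <- -flipped$loadings[, c(1, 3)]
  t2 <- compute_tpd(flipped, prep, ref_id)
  expect_equal(t1$tpd, t2$tpd, tolerance = 1e-10)
  expect_error(compute_tpd(pca, prep, "nope"), "reference")
})

test_that("ANOVA on TPD: degenerate equality, constructed separation, permutation oracle", {
  set.seed(42)
  tpd <- structure(data.frame(specimen_id = sprintf("s%d", 1:12),
                              scan_index = 0L,
                              tpd = rep(2.5, 12)),
                   class = c("tpd_result", "data.frame"))
  av <- anova_tpd(tpd, rep(c("a", "b", "c"), each = 4))
  expect_equal(av$F, 0)
  expect_equal(av$p, 1)

  # two groups shifted by 10 pooled SDs
  vals <- c(rnorm(20, 0, 1), rnorm(20, 10, 1))
  tpd2 <- tpd[rep(1, 40), ]; tpd2$tpd <- vals
  av2 <- anova_tpd(tpd2, rep(c("lo", "hi"), each = 20))
  expect_lt(av2$p, 1e-6)

  # classical p matches a permutation p within Monte-Carlo error
  set.seed(43)
  vals3 <- c(rnorm(8, 0), rnorm(8, 0.9), rnorm(8, 0.4))
  g3 <- rep(c("a", "b", "c"), each = 8)
  tpd3 <- tpd[rep(1, 24), ]; tpd3$tpd <- vals3
  p_classic <- anova_tpd(tpd3, g3)$p
  p_perm <- perm_anova_p(vals3, g3, n_perm = 10000, seed = 7)
  expect_lt(abs(p_classic - p_perm), 3 * sqrt(p_perm * (1 - p_perm) / 10000) + 0.01)
  expect_error(anova_tpd(tpd3, rep("a", 24)), "2 groups")
  expect_error(anova_tpd(tpd3, c("a", rep(c("b", "c"), length.out = 23))),
               ">= 2 members")
})

test_that("Tukey HSD: pair count, identical-group p = 1, family-wise dominance", {
  base <- data.frame(specimen_id = "s", scan_index = 0L, tpd = 0)
  mk_tpd <- function(v) { d <- base[rep(1, length(v)), ]; d$tpd <- v
    class(d) <- c("tpd_result", "data.frame"); d }

  # k groups -> k(k-1)/2 comparisons
  set.seed(44)
  v <- rnorm(20)
  g <- rep(letters[1:5], each = 4)
  cmp <- tukey_pairwise(mk_tpd(v), g)
  expect_equal(nrow(cmp), choose(5, 2))
  expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))

  # identical groups: every p = 1
  cmp0 <- tukey_pairwise(mk_tpd(rep(3.3, 12)), rep(c("a", "b", "c"), each = 4))
  expect_true(all(abs(cmp0$p_value - 1) < 1e-9))
  expect_true(all(cmp0$mean_difference == 0))

  # Tukey p >= unadjusted two-sample p on the same pair (family-wise control)
  set.seed(45)
  v2 <- c(rnorm(6, 0), rnorm(6, 1), rnorm(6, 2))
  g2 <- rep(c("a", "b", "c"), each = 6)
  cmp2 <- tukey_pairwise(mk_tpd(v2), g2)
  s2p <- sqrt(sum((v2 - ave(v2, g2))^2) / 15)   # pooled within-group sd
  for (i in seq_len(nrow(cmp2))) {
    ga <- cmp2$group_a[i]; gb <- cmp2$group_b[i]
    tt <- abs(mean(v2[g2 == gb]) - mean(v2[g2 == ga])) /
      (s2p * sqrt(2 / 6))
    p_unadj <- 2 * stats::pt(-tt, df = 15)
    expect_gte(cmp2$p_value[i] + 1e-10, p_unadj)
  }
})

test_that("drift-free stability runs yield uniform ANOVA p-values under the null", {
  # stability design: one specimen re-scanned over storage weeks with the
  # time-zero measurement as TPD reference; no drift is simulated, so the
  # week effect is null and p should be U(0,1)
  set.seed(46)
  pvals <- replicate(120, {
    weeks <- 5; scans <- 8; p <- 40    # wk0 is the time-zero reference
    X <- matrix(rnorm(weeks * scans * p, 10, 0.5), weeks * scans)
    ids <- rep(sprintf("wk%d", seq_len(weeks) - 1L), each = scans)
    md <- data.frame(specimen_id = unique(ids), class_label = unique(ids),
                     dataset = "stability", stringsAsFactors = FALSE)
    spectra <- lapply(seq_len(nrow(X)), function(i)
      raman_spectrum(seq(400, length.out = p), X[i, ], ids[i],
                     (i - 1) %% scans))
    set <- assemble_set(spectra, md, "strict")
    pca <- fit_pca(set)
    tpd <- compute_tpd(pca, set, "wk0")
    # the reference week is the yardstick, not a comparison group: its scans
    # sit closer to their own mean by construction
    keep <- tpd$specimen_id != "wk0"
    anova_tpd(tpd[keep, ], ids[keep])$p
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})
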