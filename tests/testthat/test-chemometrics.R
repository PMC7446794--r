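test_that("PCA matches a brute-force covariance eigendecomposition on toy matrices", {
  set.seed(11)
  for (dims in list(c(6, 4), c(10, 10), c(5, 9))) {
    X <- matrix(rnorm(prod(dims)), dims[1])
    set <- toy_set(X, rep(c("A", "B"), length.out = dims[1]))
    fit <- fit_pca(set)
    ref <- pca_bruteforce(X)
    r <- fit$n_components
    for (j in seq_len(r)) {
      # eigenvectors agree up to sign
      expect_lt(min(sum((fit$loadings[, j] - ref$loadings[, j])^2),
                    sum((fit$loadings[, j] + ref$loadings[, j])^2)), 1e-16)
      expect_lt(min(max(abs(fit$scores[, j] - ref$scores[, j])),
                    max(abs(fit$scores[, j] + ref$scores[, j]))), 1e-8)
    }
    expect_equal(fit$explained_variance_fraction,
                 ref$variance_fraction[seq_len(r)], tolerance = 1e-10)
  }
})

test_that("PCA model satisfies its structural invariants", {
  set.seed(12)
  X <- matrix(rnorm(8 * 30), 8)
  fit <- fit_pca(toy_set(X, rep(c("A", "B"), 4)))
  expect_equal(fit$n_components, 7L)                       # n - 1
  I <- crossprod(fit$loadings)
  expect_lt(max(abs(I - diag(ncol(I)))), 1e-8)             # orthonormal
  ev <- fit$explained_variance_fraction
  expect_true(all(diff(ev) <= 1e-12))                      # non-increasing
  expect_lte(sum(ev), 1 + 1e-12)
  # reconstruction with all components reproduces the centered data
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(fit$scores %*% t(fit$loadings) - Xc)), 1e-8)
  # sign convention: largest-magnitude element of every loading is positive
  expect_true(all(apply(fit$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("two distinct spectra give one non-degenerate component; rank-1 data puts >99% on PC1", {
  X2 <- rbind(rnorm(12), rnorm(12))
  fit2 <- fit_pca(toy_set(X2, c("A", "B")))
  expect_equal(fit2$n_components, 1L)
  expect_error(fit_pca(toy_set(X2[1, , drop = FALSE], "A")), "at least 2")

  set.seed(13)
  dir <- rnorm(40); dir <- dir / sqrt(sum(dir^2))
  X <- outer(rnorm(15, sd = 5), dir) + matrix(rnorm(15 * 40, sd = 0.01), 15)
  fit <- fit_pca(toy_set(X, rep(c("A", "B", "C"), 5)))
  expect_gt(fit$explained_variance_fraction[1], 0.99)
})

test_that("projection is consistent, zero at the mean, and norm-contracting", {
  set.seed(14)
  X <- matrix(rnorm(6 * 25), 6)
  set <- toy_set(X, rep(c("A", "B"), 3))
  fit <- fit_pca(set)
  expect_equal(max(abs(project(fit, raman_spectrum(set$grid,
                                                   fit$mean_spectrum)))), 0,
               tolerance = 1e-10)
  # training spectrum reproduces its stored score
  expect_equal(project(fit, row_spec(set, 3)), fit$scores[3, ],
               tolerance = 1e-10)
  # orthonormal projection cannot grow the norm
  v <- row_spec(set, 2)
  centered <- v$intensities - fit$mean_spectrum
  expect_lte(sqrt(sum(project(fit, v)^2)), sqrt(sum(centered^2)) + 1e-12)
  expect_error(project(fit, raman_spectrum(1:25, rnorm(25))), "grid")
  expect_error(project(fit, v, n_pcs = 99), "exceeds")
})

test_that("DAPC separates a constructed two-class effect and is permutation-invariant", {
  set.seed(15)
  n <- 10; p <- 60
  effect <- c(rep(0, 20), 5, 10, 5, rep(0, p - 23))   # one strong band
  X <- rbind(matrix(rnorm(n * p, 10), n),
             matrix(rnorm(n * p, 10), n) + rep(effect, each = n))
  labels <- rep(c("neg", "pos"), each = n)
  set <- toy_set(X, labels)
  fit <- fit_dapc(set, n_pcs = 5)
  z <- fit$scores[, 1]
  sep <- abs(diff(tapply(z, labels, mean)))
  pooled_sd <- sqrt(mean(tapply(z, labels, var)))
  expect_gt(sep / pooled_sd, 5)

  perm <- sample(nrow(X))
  fit_p <- fit_dapc(toy_set(X[perm, ], labels[perm]), n_pcs = 5)
  agree <- min(max(abs(fit_p$canonical_coefficients -
                         fit$canonical_coefficients)),
               max(abs(fit_p$canonical_coefficients +
                         fit$canonical_coefficients)))
  expect_lt(agree, 1e-6)
})

test_that("k classes yield k-1 canonical axes and class-size guards hold", {
  set.seed(16)
  X <- matrix(rnorm(12 * 30), 12)
  fit3 <- fit_dapc(toy_set(X, rep(c("A", "B", "C"), 4)), n_pcs = 6)
  expect_equal(ncol(fit3$canonical_coefficients), 2L)
  expect_equal(nrow(fit3$class_centroids), 3L)
  expect_error(fit_dapc(toy_set(X, rep("A", 12)), 3), "2 classes")
  expect_error(fit_dapc(toy_set(X, c("A", rep("B", 11))), 3), ">= 2 training")
  expect_error(fit_dapc(toy_set(X, rep(c("A", "B"), 6)), n_pcs = 50),
               "exceeds")
})

test_that("DAPC on 1 PC / 2 classes reproduces the closed-form Fisher midpoint rule", {
  set.seed(17)
  x <- c(rnorm(12, 0), rnorm(12, 3))
  labels <- rep(c("lo", "hi"), each = 12)
  # embed the 1-D structure in a 2-column set so PCA keeps 1 component
  X <- cbind(x, 0.5 * x + 2)
  set <- toy_set(X, labels)
  fit <- fit_dapc(set, n_pcs = 1)
  thr <- fisher_threshold_1d(fit$pca$scores[, 1], labels)
  pred <- vapply(seq_len(nrow(X)), function(i)
    classify(fit, row_spec(set, i))$label, "")
  side <- ifelse(fit$pca$scores[, 1] > thr, 1, 2)
  # all points on one side of the midpoint get one label, the rest the other
  expect_equal(length(unique(pred[side == 1])), 1L)
  expect_equal(length(unique(pred[side == 2])), 1L)
  expect_false(pred[side == 1][1] == pred[side == 2][1])
})

test_that("hand-built discriminant agrees with an off-the-shelf LDA on PC scores", {
  skip_if_not_installed("MASS")
  set.seed(18)
  X <- rbind(matrix(rnorm(8 * 40), 8), matrix(rnorm(8 * 40, 0.8), 8))
  labels <- rep(c("A", "B"), each = 8)
  set <- toy_set(X, labels)
  fit <- fit_dapc(set, n_pcs = 4)
  S <- fit$pca$scores
  ref <- MASS::lda(S, grouping = labels)
  mine <- vapply(seq_len(nrow(X)), function(i)
    classify(fit, row_spec(set, i))$label, "")
  theirs <- as.character(stats::predict(ref, S)$class)
  expect_equal(mine, theirs)
})

test_that("a class centroid spectrum classifies to its own class", {
  set.seed(19)
  X <- rbind(matrix(rnorm(6 * 20, 0), 6), matrix(rnorm(6 * 20, 2), 6))
  labels <- rep(c("A", "B"), each = 6)
  set <- toy_set(X, labels)
  fit <- fit_dapc(set, n_pcs = 3)
  for (cl in c("A", "B")) {
    centroid_spec <- raman_spectrum(set$grid,
                                    colMeans(X[labels == cl, , drop = FALSE]))
    expect_equal(classify(fit, centroid_spec)$label, cl)
  }
})

test_that("training-set class separation never decreases with more PCs", {
  # the leading canonical between/within ratio is a Rayleigh quotient
  # maximized over nested score subspaces, so it is monotone in n_pcs;
  # 0/1 resubstitution accuracy tracks it up to single-point flips
  set.seed(20)
  X <- rbind(matrix(rnorm(10 * 30, 0), 10), matrix(rnorm(10 * 30, 0.5), 10))
  labels <- rep(c("A", "B"), each = 10)
  set <- toy_set(X, labels)
  fits <- lapply(1:8, function(np) fit_dapc(set, n_pcs = np))
  sep <- vapply(fits, function(f) f$eigenvalues[1], 0)
  expect_true(all(diff(sep) >= -1e-8))
  acc <- vapply(fits, function(f)
    mean(classify(f, set)$labels == labels), 0)
  expect_true(all(diff(acc) >= -1 / nrow(X) - 1e-12))
})

test_that("ties break toward the declared reference class", {
  # two exactly symmetric classes: a point equidistant from both centroids
  X <- rbind(c(0, 1), c(0, 3), c(4, 1), c(4, 3))
  set <- toy_set(X, c("neg", "neg", "pos", "pos"))
  fit <- fit_dapc(set, n_pcs = 1, reference_order = c("neg", "pos"))
  mid <- raman_spectrum(set$grid, c(2, 2))
  expect_equal(classify(fit, mid)$label, "neg")
  fit2 <- fit_dapc(set, n_pcs = 1, reference_order = c("pos", "neg"))
  expect_equal(classify(fit2, mid)$label, "pos")
})

test_that("DAPC models serialize to JSON and classify identically after reload", {
  set.seed(21)
  X <- rbind(matrix(rnorm(6 * 15, 0), 6), matrix(rnorm(6 * 15, 1.5), 6))
  set <- toy_set(X, rep(c("A", "B"), each = 6))
  fit <- fit_dapc(set, n_pcs = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_dapc_json(fit, path)
  back <- read_dapc_json(path)
  for (i in seq_len(nrow(X))) {
    a <- classify(fit, row_spec(set, i))
    b <- classify(back, row_spec(set, i))
    expect_equal(a$label, b$label)
    expect_equal(a$canonical, b$canonical, tolerance = 1e-10)
  }
})
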