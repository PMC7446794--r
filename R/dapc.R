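#' Discriminant analysis of principal components (DAPC)
#'
#' Fits PCA on the spectrum set, truncates to the leading `n_pcs` score
#' dimensions, and builds linear canonical variates (Fisher discriminant
#' axes) separating the class labels. The number of canonicals is
#' `min(n_classes - 1, n_pcs)`. The within-class scatter matrix is
#' regularized by adding `1e-8 * trace` to its diagonal when singular.
#' Canonical axes are scaled to unit pooled within-class variance, so
#' distances in canonical space are Mahalanobis-whitened; each axis carries
#' the same deterministic sign convention as the PCA loadings.
#'
#' @param set A preprocessed `spectrum_set` with >= 2 classes in its
#'   metadata, every class holding >= 2 spectra.
#' @param n_pcs Number of leading principal components fed to the
#'   discriminant (>= 1).
#' @param reference_order Optional character vector giving the tie-break
#'   precedence of class labels in [classify()]; prediction ties go to the
#'   earliest listed class (screening fails toward the reference/negative
#'   class rather than at random). Defaults to the sorted class labels.
#' @return An object of class `dapc`: list with `pca` (the truncated
#'   [fit_pca()] model), `n_pcs`, `canonical_coefficients` (n_pcs x
#'   n_canonicals), `class_centroids` (classes x canonicals), `class_labels`,
#'   `priors` (uniform), `reference_order` and the canonical training
#'   `scores`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(
#'   grid = c(380, 1850, 4), n_per_class = c(A = 5, B = 5),
#'   scans_per_specimen = 2, seed = 1))
#' prep <- preprocess_pipeline(cohort$set)
#' fit <- fit_dapc(prep, n_pcs = 4)
#' print(fit)
#' @export
fit_dapc <- function(set, n_pcs, reference_order = NULL) {
  stopifnot(n_pcs >= 1)
  labels <- set_labels(set)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("DAPC needs at least 2 classes")
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("every class needs >= 2 training spectra; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  pca <- fit_pca(set)
  if (n_pcs > pca$n_components)
    stop("n_pcs = ", n_pcs, " exceeds the ", pca$n_components,
         " available components")
  S <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  n <- nrow(S); k <- length(classes)

  means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(S[labels == cl, , drop = FALSE])))
  grand <- colMeans(S)
  W <- matrix(0, n_pcs, n_pcs)
  for (cl in classes) {
    Sc <- sweep(S[labels == cl, , drop = FALSE], 2L, means[match(cl, classes), ])
    W <- W + crossprod(Sc)
  }
  W <- W / (n - k)
  Mb <- sweep(means, 2L, grand)
  Bm <- crossprod(Mb * sqrt(as.numeric(sizes[classes]))) / (k - 1)

  ## whiten by W (regularized if near-singular), then eigendecompose between
  ew <- eigen(W, symmetric = TRUE)
  if (min(ew$values) <= 1e-12 * max(sum(diag(W)), 1e-300)) {
    ## ridge scale falls back to the total scatter when W itself is zero
    ridge <- 1e-8 * max(sum(diag(W)), sum(S^2) / max(n - 1, 1),
                        .Machine$double.xmin)
    W <- W + diag(ridge, n_pcs)
    ew <- eigen(W, symmetric = TRUE)
  }
  Wih <- ew$vectors %*% (t(ew$vectors) / sqrt(ew$values))
  eb <- eigen(Wih %*% Bm %*% t(Wih), symmetric = TRUE)
  n_can <- min(k - 1L, n_pcs)
  A <- Wih %*% eb$vectors[, seq_len(n_can), drop = FALSE]
  ## unit within-class variance per axis (Wih already whitens; rescale for
  ## numerical exactness) and fixed sign convention
  for (j in seq_len(n_can)) {
    a <- A[, j]
    a <- a / sqrt(drop(crossprod(a, W %*% a)))
    if (a[which.max(abs(a))] < 0) a <- -a
    A[, j] <- a
  }
  centroids <- means %*% A
  rownames(centroids) <- classes
  if (is.null(reference_order)) reference_order <- classes
  if (!setequal(reference_order, classes))
    stop("reference_order must be a permutation of the class labels")

  pca_t <- pca
  pca_t$loadings <- pca$loadings[, seq_len(n_pcs), drop = FALSE]
  pca_t$explained_variance_fraction <-
    pca$explained_variance_fraction[seq_len(n_pcs)]
  pca_t$n_components <- n_pcs
  pca_t$scores <- S

  structure(list(pca = pca_t, n_pcs = as.integer(n_pcs),
                 canonical_coefficients = A,
                 class_centroids = centroids,
                 class_labels = classes,
                 priors = stats::setNames(rep(1 / k, k), classes),
                 reference_order = reference_order,
                 scores = S %*% A,
                 eigenvalues = eb$values[seq_len(n_can)],
                 labels = labels),
            class = "dapc")
}

#' @export
print.dapc <- function(x, ...) {
  cat(sprintf("<dapc> %d PCs -> %d canonical axes, %d classes\n",
              x$n_pcs, ncol(x$canonical_coefficients),
              length(x$class_labels)))
  cat("  classes:", paste(x$class_labels, collapse = ", "), "\n")
  cat(sprintf("  variance retained by PCs: %.1f%%\n",
              100 * sum(x$pca$explained_variance_fraction)))
  invisible(x)
}

#' @export
summary.dapc <- function(object, ...) {
  res <- list(
    n_pcs = object$n_pcs,
    n_canonicals = ncol(object$canonical_coefficients),
    class_sizes = table(object$labels),
    variance_retained = sum(object$pca$explained_variance_fraction),
    eigenvalues = object$eigenvalues,
    centroids = object$class_centroids)
  class(res) <- "summary.dapc"
  res
}

#' @export
print.summary.dapc <- function(x, ...) {
  cat(sprintf("DAPC model: %d PCs, %d canonical axes (%.1f%% variance retained)\n",
              x$n_pcs, x$n_canonicals, 100 * x$variance_retained))
  cat("Class sizes:\n"); print(x$class_sizes)
  cat("Canonical eigenvalues (between/within):",
      sprintf("%.3g", x$eigenvalues), "\n")
  cat("Class centroids (canonical space):\n")
  print(round(x$centroids, 3))
  invisible(x)
}

#' @export
coef.dapc <- function(object, ...) object$canonical_coefficients

#' @export
plot.dapc <- function(x, axes = c(1L, 2L), ...) {
  S <- x$scores
  if (ncol(S) == 1L) {
    ds <- lapply(x$class_labels, function(cl) S[x$labels == cl, 1L])
    graphics::boxplot(ds, names = x$class_labels, ylab = "Canonical 1", ...)
  } else {
    cl <- factor(x$labels, levels = x$class_labels)
    graphics::plot(S[, axes[1L]], S[, axes[2L]], col = as.integer(cl),
                   pch = 19, xlab = paste("Canonical", axes[1L]),
                   ylab = paste("Canonical", axes[2L]), ...)
    graphics::legend("topright", legend = x$class_labels,
                     col = seq_along(x$class_labels), pch = 19, bty = "n")
  }
  invisible(x)
}

#' Classify a preprocessed spectrum with a DAPC model
#'
#' Projects the spectrum onto the model's principal components, maps the
#' scores into canonical space, and assigns the class whose centroid is
#' nearest there (the canonical space is Mahalanobis-whitened, so Euclidean
#' distance applies). Exact ties are broken toward the earliest class in the
#' model's `reference_order`.
#'
#' @param model A fitted [fit_dapc()] model.
#' @param spectrum A preprocessed [raman_spectrum] on the model grid (or a
#'   `spectrum_set` / matrix of such spectra).
#' @return For a single spectrum, a list with `label` and `canonical`
#'   coordinates; otherwise a list with `labels` and the `canonical` matrix.
#' @export
classify <- function(model, spectrum) {
  stopifnot(inherits(model, "dapc"))
  S <- project(model$pca, spectrum, model$n_pcs)
  single <- is.null(dim(S))
  if (single) S <- matrix(S, nrow = 1L)
  Z <- S %*% model$canonical_coefficients
  C <- model$class_centroids
  prec <- match(rownames(C), model$reference_order)
  labels <- vapply(seq_len(nrow(Z)), function(i) {
    d2 <- colSums((t(C) - Z[i, ])^2)
    best <- which(d2 <= min(d2) + 1e-12)          # tolerance-tied set
    rownames(C)[best[which.min(prec[best])]]
  }, "")
  if (single) list(label = labels[1L], canonical = drop(Z))
  else list(labels = labels, canonical = Z)
}

#' @export
predict.dapc <- function(object, newdata, ...) classify(object, newdata)

#' Serialize a DAPC model to portable JSON
#'
#' Writes grid, mean spectrum, loadings, canonical coefficients, centroids,
#' labels and priors to a plain JSON document readable by
#' [read_dapc_json()].
#'
#' @param model A `dapc` model.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dapc_json <- function(model, path) {
  obj <- list(
    grid = model$pca$grid,
    mean_spectrum = model$pca$mean_spectrum,
    loadings = model$pca$loadings,
    explained_variance_fraction = model$pca$explained_variance_fraction,
    n_pcs = model$n_pcs,
    canonical_coefficients = model$canonical_coefficients,
    class_centroids = model$class_centroids,
    class_labels = model$class_labels,
    priors = model$priors,
    reference_order = model$reference_order)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a DAPC model from its JSON serialization
#' @param path Path written by [write_dapc_json()].
#' @return A `dapc` model usable with [classify()] (training scores and
#'   labels are not round-tripped).
#' @export
read_dapc_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  pca <- structure(list(grid = o$grid, mean_spectrum = o$mean_spectrum,
                        loadings = as.matrix(o$loadings),
                        explained_variance_fraction =
                          o$explained_variance_fraction,
                        n_components = o$n_pcs, scores = NULL),
                   class = "raman_pca")
  centroids <- as.matrix(o$class_centroids)
  rownames(centroids) <- o$class_labels
  structure(list(pca = pca, n_pcs = o$n_pcs,
                 canonical_coefficients = as.matrix(o$canonical_coefficients),
                 class_centroids = centroids,
                 class_labels = o$class_labels,
                 priors = unlist(o$priors),
                 reference_order = o$reference_order,
                 scores = NULL, eigenvalues = NULL, labels = NULL),
            class = "dapc")
}
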