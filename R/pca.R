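#' Fit a principal component analysis on a spectrum set
#'
#' Column-mean-centered singular value decomposition of the intensity
#' matrix. Components are ordered by decreasing variance and carry a
#' deterministic sign convention: within each loading vector the element of
#' largest magnitude is positive, so results are reproducible across linear
#' algebra backends. At most `n - 1` components are retained for `n` spectra.
#'
#' @param set A `spectrum_set` with at least 2 rows.
#' @return An object of class `raman_pca`: list with `grid`, `mean_spectrum`,
#'   `loadings` (wavenumbers x components, orthonormal columns),
#'   `explained_variance_fraction` (non-increasing, sums to <= 1),
#'   `n_components`, and the training `scores` matrix.
#' @export
fit_pca <- function(set) {
  X <- set$matrix
  if (nrow(X) < 2L) stop("PCA needs at least 2 spectra")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0)
  r <- min(nrow(X) - 1L, ncol(X))
  d <- sv$d[seq_len(r)]
  V <- sv$v[, seq_len(r), drop = FALSE]
  ## sign convention: largest-magnitude loading element positive
  flip <- vapply(seq_len(r), function(j) {
    v <- V[, j]
    sign(v[which.max(abs(v))]) < 0
  }, TRUE)
  V[, flip] <- -V[, flip]
  structure(list(grid = set$grid, mean_spectrum = mu, loadings = V,
                 explained_variance_fraction = d^2 / sum(sv$d^2),
                 n_components = r,
                 scores = Xc %*% V),
            class = "raman_pca")
}

#' @export
print.raman_pca <- function(x, ...) {
  cat(sprintf("<raman_pca> %d components over %d wavenumbers\n",
              x$n_components, length(x$grid)))
  k <- min(5L, x$n_components)
  cat(sprintf("  variance explained by top %d: %s\n", k,
              paste(sprintf("%.1f%%", 100 * x$explained_variance_fraction[1:k]),
                    collapse = ", ")))
  invisible(x)
}

#' @export
plot.raman_pca <- function(x, n = 20L, ...) {
  k <- min(n, x$n_components)
  graphics::barplot(100 * x$explained_variance_fraction[seq_len(k)],
                    names.arg = seq_len(k), xlab = "Principal component",
                    ylab = "Variance explained (%)", ...)
  invisible(x)
}

#' Project spectra onto fitted principal components
#'
#' Scores are `(intensities - mean_spectrum) %*% loadings[, 1:n_pcs]`.
#'
#' @param model A `raman_pca`.
#' @param spectrum A [raman_spectrum] on the model grid, a `spectrum_set`,
#'   or a numeric matrix with one spectrum per row.
#' @param n_pcs Number of leading components (default: all).
#' @return A score matrix (rows = spectra) for matrix/set input, or a score
#'   vector for a single spectrum.
#' @export
project <- function(model, spectrum, n_pcs = model$n_components) {
  stopifnot(inherits(model, "raman_pca"), n_pcs >= 1)
  if (n_pcs > model$n_components)
    stop("n_pcs exceeds the ", model$n_components, " fitted components")
  single <- inherits(spectrum, "raman_spectrum")
  X <- if (single) {
    if (length(spectrum$wavenumbers) != length(model$grid) ||
        any(spectrum$wavenumbers != model$grid))
      stop("spectrum grid does not match the PCA model grid")
    matrix(spectrum$intensities, nrow = 1L)
  } else if (inherits(spectrum, "spectrum_set")) {
    if (length(spectrum$grid) != length(model$grid) ||
        any(spectrum$grid != model$grid))
      stop("set grid does not match the PCA model grid")
    spectrum$matrix
  } else {
    as.matrix(spectrum)
  }
  if (ncol(X) != length(model$grid)) stop("grid mismatch")
  S <- sweep(X, 2L, model$mean_spectrum) %*%
    model$loadings[, seq_len(n_pcs), drop = FALSE]
  if (single) drop(S) else S
}

#' @export
predict.raman_pca <- function(object, newdata, n_pcs = object$n_components, ...) {
  project(object, newdata, n_pcs)
}
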