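#' Preprocessing configuration
#'
#' Parameters of the spectral processing chain. Defaults are the published
#' operating point of the pipeline: truncation to 400-1800 cm^-1, baseline
#' polynomial order 3, estimated peak ratio 0.5, smoothing window 5 points.
#'
#' @param trunc_low,trunc_high Truncation interval in cm^-1; points with
#'   `trunc_low <= w < trunc_high` are retained (half-open, so a 1 cm^-1
#'   integer grid yields exactly 1400 points).
#' @param poly_order Baseline polynomial degree (>= 0).
#' @param peak_ratio Estimated fraction of points occupied by peaks, in (0,1).
#' @param smooth_window Odd smoothing window (points) applied before the
#'   baseline fit (a centered local-polynomial smoother of the baseline's
#'   order, so smoothing never biases the baseline); 1 disables smoothing.
#' @param max_iter Maximum IRLS iterations per baseline fit.
#' @param tol Relative coefficient-change convergence threshold.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(trunc_low = 400, trunc_high = 1800,
                              poly_order = 3L, peak_ratio = 0.5,
                              smooth_window = 5L, max_iter = 100L,
                              tol = 1e-6) {
  stopifnot(trunc_low < trunc_high, poly_order >= 0,
            peak_ratio > 0, peak_ratio < 1,
            smooth_window >= 1, smooth_window %% 2 == 1,
            max_iter >= 1, tol > 0)
  structure(list(trunc_low = trunc_low, trunc_high = trunc_high,
                 poly_order = as.integer(poly_order), peak_ratio = peak_ratio,
                 smooth_window = as.integer(smooth_window),
                 max_iter = as.integer(max_iter), tol = tol),
            class = "preprocess_config")
}

#' Truncate a spectrum to a wavenumber window
#'
#' Retains exactly the points with `low <= w < high` (half-open interval),
#' preserving order. Idempotent.
#'
#' @param spectrum A [raman_spectrum].
#' @param low,high Window bounds in cm^-1.
#' @return The truncated [raman_spectrum].
#' @export
truncate_spectrum <- function(spectrum, low = 400, high = 1800) {
  keep <- spectrum$wavenumbers >= low & spectrum$wavenumbers < high
  if (sum(keep) < 2L)
    stop(sprintf("truncation to [%g, %g) leaves %d point(s)", low, high,
                 sum(keep)))
  raman_spectrum(spectrum$wavenumbers[keep], spectrum$intensities[keep],
                 spectrum$specimen_id, spectrum$scan_index)
}

## centered Savitzky-Golay smoother: local polynomial fit of degree `order`
## over a `window`-point neighborhood, evaluated at the center. Preserves
## polynomials up to `order` exactly (edges refit on the partial window), so
## smoothing never biases the subsequent baseline estimate.
smooth_sg <- function(y, window, order) {
  n <- length(y)
  if (window <= 1L || n < window) return(y)
  h <- (window - 1L) %/% 2L
  q <- min(order, window - 1L)
  X <- outer(seq(-h, h), 0:q, `^`)
  k <- (X %*% solve(crossprod(X), t(X)))[h + 1L, ]  # center-value kernel
  ys <- as.numeric(stats::filter(y, k, sides = 2L))
  for (i in c(seq_len(h), seq(n - h + 1L, n))) {    # partial edge windows
    idx <- max(1L, i - h):min(n, i + h)
    Xe <- outer(idx - i, 0:min(q, length(idx) - 1L), `^`)
    ys[i] <- (Xe %*% solve(crossprod(Xe), crossprod(Xe, y[idx])))[idx == i]
  }
  ys
}

## IRLS polynomial fit under an asymmetric capped-quadratic loss.
## Residuals r = y - baseline: r <= s cost r^2 (weight 1); r > s cost capped
## at s^2 (weight (s/r)^2), so peaks stop attracting the baseline.
## B is an orthonormal polynomial basis. Returns coefficients + convergence.
fit_capped_poly <- function(B, y, s, a0, max_iter, tol) {
  a <- a0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y - drop(B %*% a)
    w <- rep(1, length(y))
    over <- r > s
    w[over] <- (s / r[over])^2
    Bw <- B * w
    a_new <- solve(crossprod(B, Bw), crossprod(Bw, y))
    if (max(abs(a_new - a)) < tol * max(max(abs(a)), 1)) {
      a <- a_new
      converged <- TRUE
      break
    }
    a <- a_new
  }
  list(coef = drop(a), converged = converged)
}

#' Goldindec-style polynomial baseline correction
#'
#' Fits a degree-`poly_order` polynomial baseline to a (typically truncated)
#' spectrum by iteratively reweighted least squares under an asymmetric
#' capped-quadratic cost: points below the running baseline keep full
#' quadratic cost, while points rising more than a cap `s` above it are
#' downweighted so Raman peaks do not pull the fit upwards. The input is
#' first smoothed by a centered moving average of `smooth_window` points.
#' The cap `s` is located by a one-dimensional bisection search so that the
#' fraction of points treated as peak-like (residual above the cap) matches
#' `peak_ratio`. Iteration stops when the relative coefficient change drops
#' below `tol` or after `max_iter` sweeps; non-convergence sets a warning
#' flag on the result rather than raising an error.
#'
#' @param spectrum A [raman_spectrum] (already truncated).
#' @param cfg A [preprocess_config()].
#' @return A list with `baseline` (numeric vector on the spectrum grid),
#'   `corrected` (a [raman_spectrum] with the baseline subtracted),
#'   `coefficients` (in the orthonormal internal basis), `cap` (the selected
#'   asymmetric-loss cap) and `converged` (logical).
#' @export
goldindec_baseline <- function(spectrum, cfg = preprocess_config()) {
  y <- smooth_sg(spectrum$intensities, cfg$smooth_window, cfg$poly_order)
  x <- spectrum$wavenumbers
  n <- length(y)
  p <- min(cfg$poly_order, n - 1L)
  ## orthonormal polynomial basis on the grid (well-conditioned at any order)
  xs <- 2 * (x - min(x)) / (max(x) - min(x)) - 1
  B <- qr.Q(qr(outer(xs, 0:p, `^`)))
  a_ols <- drop(crossprod(B, y))
  r0 <- y - drop(B %*% a_ols)
  rng <- max(r0) - min(r0)
  if (rng <= 0) {  # exactly polynomial input: OLS fit is the baseline
    base <- drop(B %*% a_ols)
    return(list(baseline = base,
                corrected = raman_spectrum(x, spectrum$intensities - base,
                                           spectrum$specimen_id,
                                           spectrum$scan_index),
                coefficients = a_ols, cap = 0, converged = TRUE))
  }
  s_lo <- 1e-4 * rng
  s_hi <- max(r0) + rng
  peak_frac <- function(fit, s) mean(y - drop(B %*% fit$coef) > s)
  a_warm <- a_ols
  eval_at <- function(s) {
    fit <- fit_capped_poly(B, y, s, a_warm, cfg$max_iter, cfg$tol)
    a_warm <<- fit$coef
    fit
  }
  fit_hi <- eval_at(s_hi)
  if (peak_frac(fit_hi, s_hi) >= cfg$peak_ratio) {
    fit <- fit_hi; s <- s_hi
  } else {
    fit_lo <- eval_at(s_lo)
    if (peak_frac(fit_lo, s_lo) <= cfg$peak_ratio) {
      fit <- fit_lo; s <- s_lo
    } else {
      lo <- s_lo; hi <- s_hi; fit <- fit_lo; s <- s_lo
      for (k in 1:24) {      # bisection on the peak-like fraction
        s <- (lo + hi) / 2
        fit <- eval_at(s)
        if (peak_frac(fit, s) > cfg$peak_ratio) lo <- s else hi <- s
        if ((hi - lo) < 1e-3 * rng) break
      }
    }
  }
  base <- drop(B %*% fit$coef)
  if (!fit$converged)
    warning("baseline fit did not converge within max_iter")
  list(baseline = base,
       corrected = raman_spectrum(x, spectrum$intensities - base,
                                  spectrum$specimen_id, spectrum$scan_index),
       coefficients = fit$coef, cap = s, converged = fit$converged)
}

#' Vector-normalize a spectrum to unit Euclidean norm
#'
#' @param spectrum A [raman_spectrum]; must not be all-zero.
#' @return The normalized [raman_spectrum] (`sqrt(sum(I^2)) == 1`).
#' @export
vector_normalize <- function(spectrum) {
  nrm <- sqrt(sum(spectrum$intensities^2))
  if (nrm == 0) stop("cannot vector-normalize an all-zero spectrum")
  raman_spectrum(spectrum$wavenumbers, spectrum$intensities / nrm,
                 spectrum$specimen_id, spectrum$scan_index)
}

#' Average replicate scans within each specimen
#'
#' Collapses a spectrum set to one row per specimen: the pointwise mean of
#' that specimen's scans (equal weight per scan). Intended for sets that are
#' already truncated, baseline-corrected and vector-normalized.
#'
#' @param set A `spectrum_set`.
#' @return A `spectrum_set` with one row per specimen (`scan_index` 0).
#' @export
average_replicates <- function(set) {
  ids <- unique(set$specimen_ids)
  m <- do.call(rbind, lapply(ids, function(id)
    colMeans(set$matrix[set$specimen_ids == id, , drop = FALSE])))
  new_spectrum_set(set$grid, m, ids, rep(0L, length(ids)), set$metadata)
}

#' Run the full spectral processing chain
#'
#' Applies, in order: truncation, Goldindec-style baseline correction,
#' vector normalization and (optionally) replicate averaging — the standard
#' chain applied to every urine spectrum before chemometric modelling.
#' `average = FALSE` supports analyses run on unaveraged replicate scans,
#' as the TPD statistics are.
#'
#' @param set A raw `spectrum_set`.
#' @param cfg A [preprocess_config()].
#' @param average Collapse replicate scans to one spectrum per specimen?
#' @return The processed `spectrum_set`.
#' @export
preprocess_pipeline <- function(set, cfg = preprocess_config(), average = TRUE) {
  keep <- set$grid >= cfg$trunc_low & set$grid < cfg$trunc_high
  if (sum(keep) < 2L)
    stop("truncation window retains fewer than 2 grid points")
  g <- set$grid[keep]
  m <- set$matrix[, keep, drop = FALSE]
  for (i in seq_len(nrow(m))) {
    s <- raman_spectrum(g, m[i, ])
    bc <- goldindec_baseline(s, cfg)
    v <- bc$corrected$intensities
    nrm <- sqrt(sum(v^2))
    if (nrm == 0) stop("row ", i, " is all-zero after baseline correction")
    m[i, ] <- v / nrm
  }
  out <- new_spectrum_set(g, m, set$specimen_ids, set$scan_indices,
                          set$metadata)
  if (average) average_replicates(out) else out
}
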