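#' Confusion counts for a binary screen
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true/false positives and
#'   negatives against the gold-standard diagnosis).
#' @return A list of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = unname(tp), fp = unname(fp), fn = unname(fn), tn = unname(tn))
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(lapply(as.list(v), as.integer), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d fn=%d tn=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$tp + x$fp + x$fn + x$tn))
  invisible(x)
}

#' Screening metrics from confusion counts
#'
#' Computes the five screening percentages:
#' accuracy `(tp+tn)/n`, sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' positive predictive value `tp/(tp+fp)` and negative predictive value
#' `tn/(tn+fn)`, each times 100. A ratio with a zero denominator is reported
#' as `NA` (never as 0). Values are kept at full precision; the print method
#' rounds to 1 decimal for reporting.
#'
#' @param counts A [confusion_counts()].
#' @param n_pcs,variance_explained Optional annotations recording the model
#'   the counts came from.
#' @return A list of class `screen_metrics` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv` (percent), plus `counts`,
#'   `n_pcs`, `variance_explained`.
#' @examples
#' m <- metrics_from_confusion(confusion_counts(tp = 14, fp = 8, fn = 3, tn = 31))
#' print(m)  # accuracy 80.4, sensitivity 82.4, specificity 79.5, ...
#' @export
metrics_from_confusion <- function(counts, n_pcs = NA_integer_,
                                   variance_explained = NA_real_) {
  stopifnot(inherits(counts, "confusion_counts"))
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  with(counts, structure(list(
    accuracy = rate(tp + tn, tp + fp + fn + tn),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn),
    counts = counts,
    n_pcs = as.integer(n_pcs),
    variance_explained = variance_explained),
    class = "screen_metrics"))
}

#' @export
print.screen_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", round(v, 1))
  if (!is.na(x$n_pcs)) cat(sprintf("DAPC model with %d PCs", x$n_pcs))
  else cat("Screen metrics")
  if (!is.na(x$variance_explained))
    cat(sprintf(" (%.1f%% variance explained)", x$variance_explained))
  cat(":\n")
  cat(sprintf("  accuracy %s  sensitivity %s  specificity %s  PPV %s  NPV %s\n",
              fmt(x$accuracy), fmt(x$sensitivity), fmt(x$specificity),
              fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' @export
as.data.frame.screen_metrics <- function(x, ...) {
  data.frame(n_pcs = x$n_pcs, accuracy = x$accuracy,
             sensitivity = x$sensitivity, specificity = x$specificity,
             ppv = x$ppv, npv = x$npv,
             variance_explained = x$variance_explained,
             tp = x$counts$tp, fp = x$counts$fp, fn = x$counts$fn,
             tn = x$counts$tn)
}

## binary tally of multiclass predictions against gold-standard labels:
## positive_class vs. everything else, with control classes excluded
tally_confusion <- function(truth, predicted, positive_class, control_classes) {
  keep <- !(truth %in% control_classes)
  truth <- truth[keep]; predicted <- predicted[keep]
  gold_pos <- truth == positive_class
  pred_pos <- predicted == positive_class
  confusion_counts(tp = sum(gold_pos & pred_pos),
                   fp = sum(!gold_pos & pred_pos),
                   fn = sum(gold_pos & !pred_pos),
                   tn = sum(!gold_pos & !pred_pos))
}

#' Leave-one-out screening evaluation
#'
#' The cross-validation engine of the screen: each specimen is removed in
#' turn, PCA and DAPC are refit from scratch on the remaining specimens with
#' `n_pcs` components, and the held-out spectrum is classified as an
#' unknown. The held-out spectrum never influences the PCA mean, loadings or
#' discriminant fit of its fold. Predictions are tallied into binary
#' screening counts: the gold-standard `positive_class` versus everything
#' else, with specimens of `control_classes` (e.g. the synthetic urinalysis
#' control) participating in model fitting as their own class but excluded
#' from the confusion counts.
#'
#' @param set A preprocessed, replicate-averaged `spectrum_set` (one row per
#'   specimen, >= 2 classes).
#' @param n_pcs Components per fold; must be <= n_specimens - 2 so every
#'   fold's model is non-degenerate.
#' @param positive_class Gold-standard positive label.
#' @param control_classes Labels excluded from the binary counts
#'   (default `"Surine"`).
#' @return A list of class `loo_result`: `predictions` (data.frame
#'   specimen_id, truth, predicted), `counts` ([confusion_counts()]),
#'   `metrics` ([metrics_from_confusion()]) and `n_pcs`.
#' @export
leave_one_out <- function(set, n_pcs, positive_class,
                          control_classes = "Surine") {
  if (anyDuplicated(set$specimen_ids))
    stop("leave_one_out expects one averaged spectrum per specimen")
  k <- n_spectra(set)
  if (n_pcs >= k - 1L)
    stop("n_pcs must be < n_specimens - 1 for non-degenerate folds")
  labels <- set_labels(set)
  if (!positive_class %in% labels) stop("positive_class not present in set")
  ref_order <- c(sort(setdiff(unique(labels), positive_class)),
                 positive_class)  # ties fail toward the non-positive classes
  predicted <- character(k)
  for (i in seq_len(k)) {
    fit <- fit_dapc(subset_rows(set, -i), n_pcs, reference_order = ref_order)
    predicted[i] <- classify(fit, row_spectrum(set, i))$label
  }
  counts <- tally_confusion(labels, predicted, positive_class, control_classes)
  structure(list(
    predictions = data.frame(specimen_id = set$specimen_ids, truth = labels,
                             predicted = predicted,
                             stringsAsFactors = FALSE),
    counts = counts,
    metrics = metrics_from_confusion(counts, n_pcs = n_pcs),
    n_pcs = as.integer(n_pcs)), class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("Leave-one-out over %d specimens (%d PCs)\n",
              nrow(x$predictions), x$n_pcs))
  print(x$metrics)
  invisible(x)
}

#' Sweep the number of principal components in the screen
#'
#' Runs [leave_one_out()] at each component count and annotates every row
#' with the cumulative variance explained by those components in the
#' full-data PCA.
#'
#' @inheritParams leave_one_out
#' @param n_pcs_range Integer vector of component counts (made strictly
#'   increasing).
#' @return A data.frame of class `pc_sweep` with one row per n_pcs:
#'   the five metrics, variance explained and confusion counts.
#' @export
sweep_pc_counts <- function(set, n_pcs_range, positive_class,
                            control_classes = "Surine") {
  n_pcs_range <- sort(unique(as.integer(n_pcs_range)))
  cumvar <- cumsum(fit_pca(set)$explained_variance_fraction) * 100
  rows <- lapply(n_pcs_range, function(np) {
    r <- leave_one_out(set, np, positive_class, control_classes)
    m <- r$metrics
    m$variance_explained <- cumvar[np]
    as.data.frame(m)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pc_sweep", "data.frame")
  out
}

#' @export
plot.pc_sweep <- function(x, ...) {
  metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  graphics::matplot(x$n_pcs, as.matrix(x[metrics]), type = "b", pch = 19,
                    lty = 1, xlab = "Number of PCs", ylab = "Metric (%)",
                    ylim = c(0, 100), ...)
  graphics::legend("bottomright", legend = metrics, col = seq_along(metrics),
                   lty = 1, pch = 19, bty = "n")
  invisible(x)
}
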