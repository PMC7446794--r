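# Shared fixtures, generated in code. Unit tests run on coarse grids for
# speed; the acceptance tests use the full-scale study conditions.

## small labelled cohort on a coarse grid
small_config <- function(seed, n_pos = 6, n_neg = 6, scans = 3,
                         step = 2, ...) {
  synthetic_config(grid = c(380, 1850, step),
                   n_per_class = c("BCA-positive" = n_pos,
                                   "BCA-negative" = n_neg),
                   scans_per_specimen = scans, seed = seed, ...)
}

## deterministic tiny spectrum set built directly from a matrix
toy_set <- function(X, labels, grid = NULL) {
  n <- nrow(X)
  grid <- grid %||% seq(400, length.out = ncol(X))
  ids <- sprintf("s%02d", seq_len(n))
  md <- data.frame(specimen_id = ids, class_label = labels,
                   dataset = "toy", stringsAsFactors = FALSE)
  spectra <- lapply(seq_len(n), function(i)
    raman_spectrum(grid, X[i, ], specimen_id = ids[i], scan_index = 0L))
  assemble_set(spectra, md, "strict")
}

## random band position in 450-1750 cm^-1, resolvable from the default
## urine peak set (>= 25 cm^-1 from every default band center)
planted_center <- function() {
  existing <- vapply(default_peak_set("none"), `[[`, 0, "center")
  repeat {
    cc <- round(runif(1, 450, 1750))
    if (min(abs(cc - existing)) >= 25) return(cc)
  }
}

## one row of a spectrum set as a raman_spectrum
row_spec <- function(set, i) {
  raman_spectrum(set$grid, set$matrix[i, ], set$specimen_ids[i],
                 set$scan_indices[i])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
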