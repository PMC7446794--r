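#' Per-wavenumber contributions to PCA or DAPC directions
#'
#' Quantifies how much each Raman shift contributes to a model direction.
#' For `space = "pca"` the directions are the top `n_components` loading
#' vectors; for `space = "dapc"` they are the canonical discriminant axes
#' mapped back to wavenumber space (loadings composed with the canonical
#' coefficients), i.e. the axes that separate the classification groups.
#' The contribution of wavenumber w to a direction is its absolute weight
#' as a percentage of the direction's total absolute weight, so each
#' component's contributions sum to 100. Wavenumbers whose contribution
#' exceeds `threshold` percent are flagged as the major contributors
#' (default 0.3%).
#'
#' @param model A fitted [fit_dapc()] model.
#' @param space `"pca"` or `"dapc"`.
#' @param n_components How many leading directions to profile (default:
#'   up to 4, the convention used when reporting molecular signatures).
#' @param threshold Percent contribution above which a band is flagged.
#' @return A data.frame of class `contribution_profile` with columns
#'   `wavenumber`, `component_id`, `contribution` (percent),
#'   `above_threshold`.
#' @export
shift_contributions <- function(model, space = c("pca", "dapc"),
                                n_components = NULL, threshold = 0.3) {
  space <- match.arg(space)
  stopifnot(inherits(model, "dapc"))
  D <- if (space == "pca") model$pca$loadings
       else model$pca$loadings %*% model$canonical_coefficients
  if (is.null(n_components)) n_components <- min(4L, ncol(D))
  if (n_components > ncol(D))
    stop("n_components exceeds the ", ncol(D), " available ", space,
         " directions")
  out <- do.call(rbind, lapply(seq_len(n_components), function(j) {
    a <- abs(D[, j])
    contrib <- 100 * a / sum(a)
    data.frame(wavenumber = model$pca$grid, component_id = j,
               contribution = contrib,
               above_threshold = contrib > threshold)
  }))
  attr(out, "space") <- space
  attr(out, "threshold") <- threshold
  class(out) <- c("contribution_profile", "data.frame")
  out
}

#' Reference Raman band assignments for urine constituents
#'
#' The built-in band table used for molecular annotation of contribution
#' profiles: phosphatidylinositol (576 cm^-1), cholesterol and fatty acids
#' (702, 1297), nucleic acids (721, 827, 1340), protein/collagen (817, 981,
#' 1065, 1127, 1340), aromatic amino acids (827, 1004), monosaccharides
#' (846), glycogen (1048) and carotenoids (1417, 1518).
#'
#' @return A data.frame with columns `wavenumber`, `molecule_class`.
#' @export
default_band_table <- function() {
  data.frame(
    wavenumber = c(576, 702, 1297, 721, 827, 1340, 817, 981, 1065, 1127,
                   1340, 827, 1004, 846, 1048, 1417, 1518),
    molecule_class = c("phosphatidylinositol",
                       "cholesterol and fatty acids",
                       "cholesterol and fatty acids",
                       "nucleic acids", "nucleic acids", "nucleic acids",
                       "protein (collagen)", "protein (collagen)",
                       "protein (collagen)", "protein (collagen)",
                       "protein (collagen)",
                       "aromatic amino acids", "aromatic amino acids",
                       "monosaccharides", "glycogen",
                       "carotenoids", "carotenoids"),
    stringsAsFactors = FALSE)
}

#' Annotate contribution profiles with molecular band assignments
#'
#' Each above-threshold wavenumber is matched against a reference band
#' table; every molecule class whose band lies within `tolerance` cm^-1 is
#' attached (a wavenumber can carry several assignments, e.g. 1340 cm^-1 is
#' listed for both nucleic acids and collagen). Wavenumbers with no match
#' are annotated `"unassigned"`.
#'
#' @param profile A [shift_contributions()] result.
#' @param table Band table (columns `wavenumber`, `molecule_class`);
#'   defaults to [default_band_table()].
#' @param tolerance Matching half-width in cm^-1 (default 5).
#' @return The profile restricted to above-threshold rows, with an
#'   `assignments` column (comma-separated molecule classes).
#' @export
assign_bands <- function(profile, table = default_band_table(),
                         tolerance = 5) {
  stopifnot(nrow(table) >= 1L,
            all(c("wavenumber", "molecule_class") %in% names(table)))
  if (anyDuplicated(table[c("wavenumber", "molecule_class")]))
    stop("band table entries must be unique per (wavenumber, molecule_class)")
  hits <- profile[profile$above_threshold, , drop = FALSE]
  hits$assignments <- vapply(hits$wavenumber, function(w) {
    cls <- unique(table$molecule_class[abs(table$wavenumber - w) <= tolerance])
    if (length(cls)) paste(cls, collapse = ", ") else "unassigned"
  }, "")
  rownames(hits) <- NULL
  hits
}
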