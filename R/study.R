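#' Run a configured screening study end to end
#'
#' Executes the full pipeline for one study configuration: obtain the cohort
#' (from spectra/metadata files or a synthetic-cohort block), preprocess,
#' run the leave-one-out screen at a fixed component count or across a
#' sweep (optionally one-vs-rest over several classes), compute TPD group
#' statistics, extract wavenumber contribution profiles, and write all
#' results plus a reproducible run manifest into `out_dir`.
#'
#' The configuration is a YAML file (or an equivalent named list) with
#' blocks:
#' \describe{
#'   \item{name}{study label.}
#'   \item{seed}{integer; mandatory when the cohort is synthetic.}
#'   \item{cohort}{either `spectra:` + `dialect:` + `metadata:` file paths,
#'     or `synthetic:` with [synthetic_config()] fields (`n_per_class`,
#'     `scans_per_specimen`, `grid`, `specimen_sd`, `scan_sd`).}
#'   \item{preprocess}{optional [preprocess_config()] overrides and
#'     `average:` flag.}
#'   \item{classification}{`positive_class:` (scalar, or a list for
#'     one-vs-rest where the other classes are considered negative) and
#'     optional `control_classes:`.}
#'   \item{analysis}{`n_pcs:` for a single model, or `sweep: [min, max]`.}
#'   \item{tpd}{optional: `reference:` specimen id, `variant:`.}
#'   \item{signatures}{optional: `space:`, `threshold:`, `n_components:`.}
#' }
#'
#' @param config Path to a YAML config file, or a named list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed results and the manifest.
#' @export
run_study <- function(config, out_dir) {
  cfg_path <- NULL
  if (is.character(config)) {
    cfg_path <- config
    config <- yaml::read_yaml(config)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  digests <- character(0)

  ## --- cohort ----------------------------------------------------------
  ch <- config$cohort
  if (!is.null(ch$synthetic)) {
    if (is.null(config$seed)) stop("synthetic cohorts require a seed")
    sc <- ch$synthetic
    args <- list(seed = config$seed)
    if (!is.null(sc$grid)) args$grid <- as.numeric(sc$grid)
    if (!is.null(sc$n_per_class)) args$n_per_class <- unlist(sc$n_per_class)
    for (f in c("scans_per_specimen", "specimen_sd", "scan_sd"))
      if (!is.null(sc[[f]])) args[[f]] <- sc[[f]]
    raw <- do.call(synthetic_config, args)
    set <- generate_cohort(raw)$set
  } else {
    if (is.null(ch$spectra) || is.null(ch$metadata))
      stop("cohort block needs either 'synthetic' or 'spectra' + 'metadata'")
    spectra <- read_spectra_table(ch$spectra, ch$dialect %||% "wide")
    md <- read_metadata(ch$metadata)
    set <- assemble_set(spectra, md,
                        grid_policy = ch$grid_policy %||% "strict")
    digests <- tools::md5sum(c(ch$spectra, ch$metadata))
  }

  ## --- preprocess ------------------------------------------------------
  pp <- config$preprocess %||% list()
  pcfg <- do.call(preprocess_config,
                  pp[intersect(names(pp), names(formals(preprocess_config)))])
  average <- pp$average %||% TRUE
  prep <- preprocess_pipeline(set, pcfg, average = average)
  prep_unavg <- if (average) preprocess_pipeline(set, pcfg, average = FALSE)
                else prep

  ## --- screening -------------------------------------------------------
  cl <- config$classification
  if (is.null(cl$positive_class)) stop("classification$positive_class required")
  positives <- unlist(cl$positive_class)
  controls <- unlist(cl$control_classes %||% "Surine")
  an <- config$analysis %||% list(n_pcs = 10L)
  results <- list()
  for (pos in positives) {
    res <- if (!is.null(an$sweep)) {
      sweep_pc_counts(prep, seq(an$sweep[[1L]], an$sweep[[2L]]), pos,
                      control_classes = controls)
    } else {
      df <- as.data.frame(leave_one_out(prep, an$n_pcs, pos,
                                        control_classes = controls)$metrics)
      df$variance_explained <-
        sum(fit_pca(prep)$explained_variance_fraction[seq_len(an$n_pcs)]) * 100
      df
    }
    res$positive_class <- pos
    results[[pos]] <- res
  }
  metrics <- do.call(rbind, results)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)

  ## --- TPD group statistics -------------------------------------------
  tpd_out <- NULL
  if (!is.null(config$tpd)) {
    pca_full <- fit_pca(prep_unavg)
    tpd <- compute_tpd(pca_full, prep_unavg, config$tpd$reference,
                       variant = config$tpd$variant %||% "abs_sum")
    grp <- set_labels(prep_unavg)
    utils::write.csv(tpd, file.path(out_dir, "tpd.csv"), row.names = FALSE)
    comp <- tukey_pairwise(tpd, grp)
    aov_res <- anova_tpd(tpd, grp)
    comp_path <- file.path(out_dir, "tpd_comparisons.csv")
    utils::write.csv(comp, comp_path, row.names = FALSE)
    tpd_out <- list(tpd = tpd, anova = aov_res[c("F", "p", "df")],
                    comparisons = comp)
  }

  ## --- contribution profiles ------------------------------------------
  sig_out <- NULL
  if (!is.null(config$signatures)) {
    sg <- config$signatures
    n_fit <- if (!is.null(an$sweep)) an$sweep[[2L]] else an$n_pcs
    model <- fit_dapc(prep, n_fit)
    prof <- shift_contributions(model, space = sg$space %||% "dapc",
                                n_components = sg$n_components,
                                threshold = sg$threshold %||% 0.3)
    annotated <- assign_bands(prof)
    utils::write.csv(prof, file.path(out_dir, "contributions.csv"),
                     row.names = FALSE)
    utils::write.csv(annotated, file.path(out_dir, "signature_bands.csv"),
                     row.names = FALSE)
    sig_out <- list(profile = prof, bands = annotated)
  }

  ## --- manifest --------------------------------------------------------
  manifest <- list(
    study = config$name %||% "unnamed",
    config = config,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ramscreen")),
    input_digests = as.list(digests),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(metrics = metrics, tpd = tpd_out, signatures = sig_out,
                 manifest = manifest, out_dir = out_dir))
}
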