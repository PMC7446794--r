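#' Construct a single Raman spectrum
#'
#' A `raman_spectrum` holds one scan of one specimen: a strictly increasing
#' wavenumber grid (cm^-1) and the matching intensity vector (arbitrary
#' units), plus the specimen identity and replicate scan index.
#'
#' @param wavenumbers Numeric vector of Raman shifts in cm^-1, finite and
#'   strictly increasing after sorting.
#' @param intensities Numeric vector of the same length; rows with
#'   non-finite intensity are rejected.
#' @param specimen_id Character scalar identifying the specimen.
#' @param scan_index Non-negative integer replicate index within specimen.
#' @return An object of class `raman_spectrum`: a list with fields
#'   `wavenumbers`, `intensities`, `specimen_id`, `scan_index`.
#' @examples
#' s <- raman_spectrum(400:500, rnorm(101, 10), "sp1", 0)
#' print(s)
#' @export
raman_spectrum <- function(wavenumbers, intensities, specimen_id = "specimen",
                           scan_index = 0L) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop("wavenumbers and intensities must have equal length")
  keep <- is.finite(intensities)
  wavenumbers <- wavenumbers[keep]
  intensities <- intensities[keep]
  if (length(wavenumbers) < 2L)
    stop("a spectrum needs at least 2 points with finite intensity")
  if (any(!is.finite(wavenumbers)))
    stop("wavenumbers must be finite")
  o <- order(wavenumbers)
  wavenumbers <- wavenumbers[o]
  intensities <- intensities[o]
  if (any(diff(wavenumbers) <= 0))
    stop("wavenumbers must be strictly increasing (duplicate grid point?)")
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         specimen_id = as.character(specimen_id),
         scan_index = as.integer(scan_index)),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> specimen %s scan %d: %d points, %.1f-%.1f cm^-1\n",
              x$specimen_id, x$scan_index, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' @export
plot.raman_spectrum <- function(x, ...) {
  graphics::plot(x$wavenumbers, x$intensities, type = "l",
                 xlab = expression(paste("Raman shift (", cm^-1, ")")),
                 ylab = "Intensity (a.u.)",
                 main = sprintf("%s / scan %d", x$specimen_id, x$scan_index), ...)
  invisible(x)
}

## Sniff the delimiter of a delimited text file: comma or tab.
detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  if (grepl("\t", first)) "\t" else ","
}

#' Read Raman spectra from a delimited text table
#'
#' Two dialects are supported. `wide`: the first column is the wavenumber,
#' every remaining column one scan, with header `specimen_id:scan_index`.
#' `long`: columns `specimen_id, scan_index, wavenumber, intensity`.
#' Comma or tab delimiters are auto-detected.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"wide"` or `"long"`.
#' @return A list of [raman_spectrum] objects, one per scan.
#' @seealso [write_spectra_table()] for the inverse operation.
#' @export
read_spectra_table <- function(path, dialect = c("wide", "long")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    if (ncol(df) < 2L)
      stop("wide spectra table needs a wavenumber column plus at least one scan")
    scan_cols <- names(df)[-1L]
    bad <- scan_cols[!grepl(":", scan_cols, fixed = TRUE)]
    if (length(bad))
      stop("malformed wide header (expected 'specimen_id:scan_index'): ",
           paste(bad, collapse = ", "))
    w <- as.numeric(df[[1L]])
    lapply(scan_cols, function(cn) {
      parts <- strsplit(cn, ":", fixed = TRUE)[[1L]]
      idx <- suppressWarnings(as.integer(parts[length(parts)]))
      if (is.na(idx))
        stop("malformed wide header (scan index not an integer): ", cn)
      raman_spectrum(w, df[[cn]],
                     specimen_id = paste(parts[-length(parts)], collapse = ":"),
                     scan_index = idx)
    })
  } else {
    need <- c("specimen_id", "scan_index", "wavenumber", "intensity")
    if (!all(need %in% names(df)))
      stop("long spectra table must have columns: ", paste(need, collapse = ", "))
    key <- paste(df$specimen_id, df$scan_index, sep = "\r")
    out <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
      raman_spectrum(d$wavenumber, d$intensity,
                     specimen_id = d$specimen_id[1L],
                     scan_index = d$scan_index[1L])
    })
    names(out) <- NULL
    out
  }
}

#' Write Raman spectra to a delimited text table
#'
#' @param spectra List of [raman_spectrum] objects. The wide dialect
#'   additionally requires all spectra to share an identical grid.
#' @param path Output file path.
#' @param dialect `"wide"` or `"long"`.
#' @param sep Field delimiter (`","` or `"\t"`).
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(spectra, path, dialect = c("wide", "long"),
                                sep = ",") {
  dialect <- match.arg(dialect)
  stopifnot(length(spectra) >= 1L)
  keys <- vapply(spectra, function(s) paste(s$specimen_id, s$scan_index,
                                            sep = ":"), "")
  if (anyDuplicated(keys))
    stop("duplicate (specimen, scan) pairs: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  if (dialect == "wide") {
    g <- spectra[[1L]]$wavenumbers
    same <- vapply(spectra, function(s)
      length(s$wavenumbers) == length(g) && all(s$wavenumbers == g), TRUE)
    if (!all(same)) stop("wide dialect requires identical grids")
    df <- data.frame(wavenumber = g, check.names = FALSE)
    for (i in seq_along(spectra)) df[[keys[i]]] <- spectra[[i]]$intensities
  } else {
    df <- do.call(rbind, lapply(spectra, function(s)
      data.frame(specimen_id = s$specimen_id, scan_index = s$scan_index,
                 wavenumber = s$wavenumbers, intensity = s$intensities)))
  }
  num <- vapply(df, is.numeric, TRUE)  # %.17g keeps doubles bit-exact
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-block JCAMP-DX spectrum
#'
#' Thin adapter for simple JCAMP-DX files: a single block whose `##XYDATA=`
#' section is either `(XY..XY)` pairs or `(X++(Y..Y))` lines with AFFN
#' (plain decimal) numbers. Compound/compressed encodings (DIF/DUP/SQZ) and
#' multi-block files are not supported.
#'
#' @param path Path to a JCAMP-DX file.
#' @param specimen_id,scan_index Identity attached to the resulting spectrum.
#' @return A [raman_spectrum].
#' @export
read_jcampdx <- function(path, specimen_id = NULL, scan_index = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  ln <- readLines(path, warn = FALSE)
  get_field <- function(key) {
    hit <- grep(paste0("^##", key, "="), ln, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^##[^=]*=", "", hit[1L]))
  }
  if (is.null(specimen_id))
    specimen_id <- get_field("TITLE") %||% basename(path)
  start <- grep("^##XYDATA=", ln, ignore.case = TRUE)
  if (length(start) != 1L)
    stop("expected exactly one ##XYDATA= block in ", path)
  form <- toupper(gsub("\\s", "", sub("^##XYDATA=", "", ln[start],
                                      ignore.case = TRUE)))
  ends <- grep("^##", ln)
  end <- ends[ends > start]
  end <- if (length(end)) min(end) - 1L else length(ln)
  body <- ln[(start + 1L):end]
  body <- body[nzchar(trimws(body))]
  xf <- as.numeric(get_field("XFACTOR") %||% "1")
  yf <- as.numeric(get_field("YFACTOR") %||% "1")
  nums <- lapply(strsplit(trimws(body), "[,;[:space:]]+"), as.numeric)
  if (any(vapply(nums, anyNA, TRUE)))
    stop("non-numeric token in XYDATA (compressed JCAMP encodings unsupported)")
  if (form == "(XY..XY)") {
    v <- unlist(nums)
    if (length(v) %% 2L != 0L) stop("odd token count in (XY..XY) data")
    w <- v[seq(1L, length(v), 2L)] * xf
    y <- v[seq(2L, length(v), 2L)] * yf
  } else {  # (X++(Y..Y)): first token per line is X, rest Y at DELTAX spacing
    dx <- get_field("DELTAX")
    dx <- if (is.null(dx)) NA_real_ else as.numeric(dx)
    if (is.na(dx)) {
      n1 <- length(nums[[1L]]) - 1L
      if (length(nums) < 2L || n1 < 1L)
        stop("cannot infer DELTAX for (X++(Y..Y)) data")
      dx <- (nums[[2L]][1L] - nums[[1L]][1L]) / n1
    }
    w <- numeric(0); y <- numeric(0)
    for (v in nums) {
      ny <- length(v) - 1L
      w <- c(w, (v[1L] + dx * (seq_len(ny) - 1L)) * xf)
      y <- c(y, v[-1L] * yf)
    }
  }
  raman_spectrum(w, y, specimen_id = specimen_id, scan_index = scan_index)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a specimen metadata table
#'
#' CSV/TSV with required columns `specimen_id`, `class_label`, `dataset`;
#' optional `sex` and `age`. Specimen ids must be unique.
#'
#' @param path Path to the metadata file.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- utils::read.table(path, header = TRUE, sep = detect_delim(path),
                          stringsAsFactors = FALSE)
  validate_metadata(md)
}

validate_metadata <- function(md) {
  need <- c("specimen_id", "class_label", "dataset")
  miss <- setdiff(need, names(md))
  if (length(miss))
    stop("metadata lacks required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$specimen_id))
    stop("duplicate specimen_id in metadata: ",
         paste(unique(md$specimen_id[duplicated(md$specimen_id)]),
               collapse = ", "))
  md$specimen_id <- as.character(md$specimen_id)
  md$class_label <- as.character(md$class_label)
  md
}

#' Assemble aligned spectra into a spectrum set
#'
#' A `spectrum_set` is the package's working container: an n_scans x
#' n_wavenumbers intensity matrix on one common grid, joined to specimen
#' metadata. With `grid_policy = "strict"` all spectra must already share an
#' identical grid and no intensity is altered; with `"intersect"` each
#' spectrum is linearly interpolated onto a common grid spanning the
#' intersection of all ranges, spaced at the median native spacing. No
#' extrapolation ever occurs.
#'
#' @param spectra Non-empty list of [raman_spectrum] objects.
#' @param metadata Data.frame with columns `specimen_id`, `class_label`,
#'   `dataset` (see [read_metadata()]); every spectrum's specimen must appear.
#' @param grid_policy `"strict"` or `"intersect"`.
#' @return An object of class `spectrum_set`: list with `grid` (common
#'   wavenumbers), `matrix` (scans x wavenumbers), `specimen_ids`,
#'   `scan_indices`, `metadata`.
#' @export
assemble_set <- function(spectra, metadata, grid_policy = c("strict", "intersect")) {
  grid_policy <- match.arg(grid_policy)
  if (!length(spectra)) stop("no spectra supplied")
  metadata <- validate_metadata(metadata)
  ids <- vapply(spectra, `[[`, "", "specimen_id")
  scans <- vapply(spectra, `[[`, 0L, "scan_index")
  key <- paste(ids, scans)
  if (anyDuplicated(key))
    stop("duplicate (specimen, scan) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  unknown <- setdiff(unique(ids), metadata$specimen_id)
  if (length(unknown))
    stop("specimens missing from metadata: ", paste(unknown, collapse = ", "))

  if (grid_policy == "strict") {
    g <- spectra[[1L]]$wavenumbers
    ok <- vapply(spectra, function(s)
      length(s$wavenumbers) == length(g) && all(s$wavenumbers == g), TRUE)
    if (!all(ok)) stop("strict grid policy: spectra grids differ")
    m <- do.call(rbind, lapply(spectra, `[[`, "intensities"))
  } else {
    lo <- max(vapply(spectra, function(s) s$wavenumbers[1L], 0))
    hi <- min(vapply(spectra, function(s)
      s$wavenumbers[length(s$wavenumbers)], 0))
    if (lo >= hi) stop("empty wavenumber intersection across spectra")
    step <- stats::median(unlist(lapply(spectra, function(s) diff(s$wavenumbers))))
    g <- seq(lo, hi, by = step)
    m <- do.call(rbind, lapply(spectra, function(s)
      stats::approx(s$wavenumbers, s$intensities, xout = g)$y))
  }
  new_spectrum_set(g, m, ids, scans, metadata)
}

new_spectrum_set <- function(grid, matrix, specimen_ids, scan_indices, metadata) {
  dimnames(matrix) <- NULL
  structure(list(grid = as.numeric(grid), matrix = matrix,
                 specimen_ids = as.character(specimen_ids),
                 scan_indices = as.integer(scan_indices),
                 metadata = metadata),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra from %d specimens, %d wavenumbers (%.1f-%.1f cm^-1)\n",
              nrow(x$matrix), length(unique(x$specimen_ids)), length(x$grid),
              min(x$grid), max(x$grid)))
  tab <- table(set_labels(x))
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of spectra (rows) in a spectrum set
#' @param set A `spectrum_set`.
#' @return Integer row count.
#' @export
n_spectra <- function(set) nrow(set$matrix)

## per-row class labels looked up from metadata
set_labels <- function(set) {
  set$metadata$class_label[match(set$specimen_ids, set$metadata$specimen_id)]
}

## row subset preserving metadata
subset_rows <- function(set, i) {
  new_spectrum_set(set$grid, set$matrix[i, , drop = FALSE],
                   set$specimen_ids[i], set$scan_indices[i], set$metadata)
}

## one row as a raman_spectrum
row_spectrum <- function(set, i) {
  raman_spectrum(set$grid, set$matrix[i, ], specimen_id = set$specimen_ids[i],
                 scan_index = set$scan_indices[i])
}
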