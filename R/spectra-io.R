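#' Construct a centroided spectrum
#'
#' A centroided spectrum is the peak-picked form of one FIA-HRMS acquisition:
#' a list of (m/z, intensity) pairs with no chromatographic or scan-time
#' dimension. Peaks are stored sorted by ascending m/z and exact duplicate
#' m/z values are merged by summing their intensities, so downstream blank
#' subtraction and alignment can assume a strictly increasing m/z vector.
#'
#' @param mz numeric vector of mass-to-charge ratios (Th); all > 0.
#' @param intensity numeric vector of ion intensities (arbitrary units);
#'   all >= 0.
#' @param label acquisition identifier (single string).
#' @param polarity ionization mode, `"positive"` or `"negative"`.
#' @return A `centroid_spectrum`: a data frame with columns `mz` and
#'   `intensity`, sorted by `mz`, carrying `label` and `polarity` attributes.
#' @examples
#' s <- centroid_spectrum(c(200, 100, 200), c(10, 50, 5), "s1", "positive")
#' s$mz        # 100, 200 (sorted, duplicates merged)
#' s$intensity # 50, 15
#' @export
centroid_spectrum <- function(mz, intensity, label = "", polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length", call. = FALSE)
  }
  if (anyNA(mz) || anyNA(intensity)) {
    stop("non-numeric value in peak list", call. = FALSE)
  }
  if (any(mz <= 0)) stop("all m/z values must be positive", call. = FALSE)
  if (any(intensity < 0)) stop("negative intensity in peak list", call. = FALSE)
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  ord <- order(mz)
  out <- data.frame(mz = mz[ord], intensity = intensity[ord])
  structure(out,
    label = as.character(label)[1L], polarity = polarity,
    class = c("centroid_spectrum", "data.frame")
  )
}

#' @export
print.centroid_spectrum <- function(x, ...) {
  cat(sprintf(
    "Centroid spectrum '%s' (%s mode): %d peaks",
    attr(x, "label"), attr(x, "polarity"), nrow(x)
  ), "\n")
  if (nrow(x) > 0L) {
    cat(sprintf(
      "  m/z %.4f..%.4f, intensity %.3g..%.3g\n",
      min(x$mz), max(x$mz), min(x$intensity), max(x$intensity)
    ))
  }
  invisible(x)
}

spectrum_label <- function(x) attr(x, "label")
spectrum_polarity <- function(x) attr(x, "polarity")

#' Read a centroided peak list from CSV
#'
#' Reads the two-column (m/z, intensity) CSV export of one acquisition.
#' The dialect is comma-separated with dot decimals; a single optional
#' header row is auto-detected by a non-numeric first row. Exact duplicate
#' m/z rows are merged by intensity sum and the result is sorted by m/z.
#'
#' @param path path to the CSV file.
#' @param label acquisition identifier; defaults to the file name without
#'   extension.
#' @param polarity ionization mode of the acquisition.
#' @return A [centroid_spectrum()].
#' @export
read_centroid_csv <- function(path, label = NULL, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) {
    stop(sprintf("peak list file not found: '%s'", path), call. = FALSE)
  }
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    stop(sprintf("empty peak list file: '%s'", path), call. = FALSE)
  }
  raw <- utils::read.csv(path,
    header = FALSE, colClasses = "character",
    strip.white = TRUE, blank.lines.skip = TRUE
  )
  if (nrow(raw) == 0L) {
    stop(sprintf("empty peak list file: '%s'", path), call. = FALSE)
  }
  if (ncol(raw) < 2L) {
    stop(sprintf("peak list '%s' must have two columns (m/z, intensity)", path), call. = FALSE)
  }
  raw <- raw[, 1:2]
  first_numeric <- !anyNA(suppressWarnings(as.numeric(unlist(raw[1L, ]))))
  if (!first_numeric) raw <- raw[-1L, , drop = FALSE]
  if (nrow(raw) == 0L) {
    stop(sprintf("peak list '%s' has a header but no data rows", path), call. = FALSE)
  }
  mz <- suppressWarnings(as.numeric(raw[[1L]]))
  intensity <- suppressWarnings(as.numeric(raw[[2L]]))
  if (anyNA(mz) || anyNA(intensity)) {
    bad <- which(is.na(mz) | is.na(intensity))[1L]
    stop(sprintf("non-numeric cell in '%s' at data row %d", path, bad), call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop(sprintf("negative intensity in '%s'", path), call. = FALSE)
  }
  if (is.null(label)) label <- tools::file_path_sans_ext(basename(path))
  centroid_spectrum(mz, intensity, label = label, polarity = polarity)
}

#' Construct an acquisition batch
#'
#' An acquisition batch is an ordered set of sample spectra, each paired
#' with the blank acquisition (carrier + extraction solvent) recorded for
#' it. Several samples may share one blank.
#'
#' @param pairs list of `list(sample =, blank =)` pairs of
#'   [centroid_spectrum()] objects.
#' @param polarity ionization mode shared by all spectra in the batch.
#' @return An `acquisition_batch` object.
#' @export
acquisition_batch <- function(pairs, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (length(pairs) == 0L) stop("acquisition batch must contain at least one pair", call. = FALSE)
  for (p in pairs) {
    stopifnot(inherits(p$sample, "centroid_spectrum"), inherits(p$blank, "centroid_spectrum"))
    if (!identical(spectrum_polarity(p$sample), polarity) ||
      !identical(spectrum_polarity(p$blank), polarity)) {
      stop("all spectra in a batch must share the batch polarity", call. = FALSE)
    }
  }
  labels <- vapply(pairs, function(p) spectrum_label(p$sample), character(1L))
  if (anyDuplicated(labels)) {
    stop("duplicate sample label in batch: ", labels[duplicated(labels)][1L], call. = FALSE)
  }
  structure(list(pairs = pairs, polarity = polarity), class = "acquisition_batch")
}

#' @export
print.acquisition_batch <- function(x, ...) {
  cat(sprintf(
    "Acquisition batch (%s mode): %d sample/blank pairs\n",
    x$polarity, length(x$pairs)
  ))
  invisible(x)
}

#' @export
length.acquisition_batch <- function(x) length(x$pairs)

batch_labels <- function(batch) {
  vapply(batch$pairs, function(p) spectrum_label(p$sample), character(1L))
}

#' Read a sample/blank manifest
#'
#' The manifest makes the sample-to-blank pairing explicit and auditable:
#' a CSV with columns `sample_file`, `blank_file`, `label`, one row per
#' sample in acquisition order. File paths are resolved relative to the
#' manifest's own directory unless absolute. The same blank file may be
#' listed for several samples; each file is read once and cached.
#'
#' @param path path to the manifest CSV.
#' @param polarity ionization mode of the batch.
#' @return An [acquisition_batch()] preserving the manifest row order.
#' @export
read_manifest <- function(path, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) {
    stop(sprintf("manifest file not found: '%s'", path), call. = FALSE)
  }
  man <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  required <- c("sample_file", "blank_file", "label")
  if (!all(required %in% names(man))) {
    stop("manifest must have columns sample_file, blank_file, label", call. = FALSE)
  }
  if (nrow(man) == 0L) stop(sprintf("empty manifest: '%s'", path), call. = FALSE)
  if (anyDuplicated(man$label)) {
    stop("duplicate label in manifest: ", man$label[duplicated(man$label)][1L], call. = FALSE)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(f) {
    if (grepl("^(/|[A-Za-z]:)", f)) f else file.path(base, f)
  }
  cache <- new.env(parent = emptyenv())
  read_cached <- function(f, label) {
    key <- normalizePath(f, mustWork = FALSE)
    if (!exists(key, envir = cache)) {
      assign(key, read_centroid_csv(f, label = label, polarity = polarity), envir = cache)
    }
    get(key, envir = cache)
  }
  pairs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    sf <- resolve(man$sample_file[i])
    bf <- resolve(man$blank_file[i])
    if (!file.exists(sf)) {
      stop(sprintf(
        "manifest row %d ('%s'): sample file not found: '%s'",
        i, man$label[i], man$sample_file[i]
      ), call. = FALSE)
    }
    if (!file.exists(bf)) {
      stop(sprintf(
        "manifest row %d ('%s'): blank file not found: '%s'",
        i, man$label[i], man$blank_file[i]
      ), call. = FALSE)
    }
    pairs[[i]] <- list(
      sample = read_centroid_csv(sf, label = man$label[i], polarity = polarity),
      blank = read_cached(bf, label = paste0("blank_", man$label[i]))
    )
  }
  acquisition_batch(pairs, polarity = polarity)
}

#' Construct a feature matrix
#'
#' A feature matrix is the aligned feature-by-sample intensity table: one
#' row per m/z feature with its sequential identifier and mean m/z, one
#' intensity column per sample. Absent intensities are `NA`.
#'
#' @param feature_id integer feature identifiers (unique).
#' @param mean_mz mean m/z of each feature (Th).
#' @param intensities numeric matrix, one column per sample, `NA` = missing.
#' @param sample_labels ordered sample identifiers (column names).
#' @param polarity ionization mode.
#' @return A `feature_matrix` data frame.
#' @export
feature_matrix <- function(feature_id, mean_mz, intensities, sample_labels,
                           polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  intensities <- as.matrix(intensities)
  stopifnot(
    length(feature_id) == length(mean_mz),
    nrow(intensities) == length(feature_id),
    ncol(intensities) == length(sample_labels)
  )
  if (anyDuplicated(feature_id)) stop("feature_id values must be unique", call. = FALSE)
  out <- data.frame(
    feature_id = as.integer(feature_id), mean_mz = as.numeric(mean_mz),
    check.names = FALSE
  )
  colnames(intensities) <- sample_labels
  out <- cbind(out, as.data.frame(intensities, check.names = FALSE))
  rownames(out) <- NULL
  structure(out,
    sample_labels = as.character(sample_labels), polarity = polarity,
    class = c("feature_matrix", "data.frame")
  )
}

matrix_sample_labels <- function(m) attr(m, "sample_labels")
matrix_polarity <- function(m) attr(m, "polarity")

# Columns of a feature matrix that hold per-sample intensities.
intensity_columns <- function(m) {
  labs <- matrix_sample_labels(m)
  if (is.null(labs)) {
    meta <- c(
      "feature_id", "mean_mz", "adduct_label", "adduct_group",
      "hmdb_accession", "metabolite_name", "adduct", "n_matches"
    )
    labs <- setdiff(names(m), meta)
  }
  labs
}

#' @export
`[.feature_matrix` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "sample_labels") <- attr(x, "sample_labels")
    attr(out, "polarity") <- attr(x, "polarity")
    class(out) <- class(x)
  }
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  labs <- intensity_columns(x)
  cat(sprintf(
    "Feature matrix (%s mode): %d features x %d samples\n",
    matrix_polarity(x), nrow(x), length(labs)
  ))
  if (inherits(x, "annotated_matrix")) {
    cat(sprintf(
      "  annotated: %d single-match, %d ambiguous, %d unannotated\n",
      sum(x$n_matches == 1L), sum(x$n_matches > 1L), sum(x$n_matches == 0L)
    ))
  }
  NextMethod()
}

#' Write a feature matrix to disk
#'
#' Writes the canonical CSV, named with the conventional suffix:
#' `_alignment_data` for a plain aligned matrix, `_alignment_data_sorted`
#' when the matrix has been regrouped by adducts, and `_HMDB_ID` for an
#' annotated matrix. Missing intensities are serialized as empty cells.
#' An `.xlsx` mirror is written alongside when the writexl package is
#' installed; the CSV is always the canonical, bit-stable artifact.
#'
#' @param matrix a `feature_matrix` or `annotated_matrix`.
#' @param basename output path prefix (directory + base name, no suffix).
#' @param sorted_by_adducts logical; use the `_alignment_data_sorted`
#'   suffix. Ignored for annotated matrices.
#' @return Invisibly, the paths written (CSV first).
#' @export
write_matrix <- function(matrix, basename, sorted_by_adducts = FALSE) {
  if (nrow(matrix) == 0L) stop("refusing to write an empty feature matrix", call. = FALSE)
  suffix <- if (inherits(matrix, "annotated_matrix")) {
    "_HMDB_ID"
  } else if (isTRUE(sorted_by_adducts)) {
    "_alignment_data_sorted"
  } else {
    "_alignment_data"
  }
  dir <- dirname(basename)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  csv_path <- paste0(basename, suffix, ".csv")
  df <- as.data.frame(matrix, check.names = FALSE)
  utils::write.csv(df, csv_path, row.names = FALSE, na = "")
  paths <- csv_path
  if (requireNamespace("writexl", quietly = TRUE)) {
    xlsx_path <- paste0(basename, suffix, ".xlsx")
    writexl::write_xlsx(df, xlsx_path)
    paths <- c(paths, xlsx_path)
  }
  invisible(paths)
}

#' Read a feature matrix back from its CSV
#'
#' Inverse of [write_matrix()] for the canonical CSV: empty cells become
#' `NA` missing markers. Annotation can thus run on any previously written
#' matrix file, not only on in-memory results.
#'
#' @param path path to a matrix CSV written by [write_matrix()].
#' @param polarity ionization mode the matrix was produced in.
#' @return A `feature_matrix`.
#' @export
read_matrix_csv <- function(path, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) stop(sprintf("matrix file not found: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = "")
  if (!all(c("feature_id", "mean_mz") %in% names(df))) {
    stop("matrix CSV must have feature_id and mean_mz columns", call. = FALSE)
  }
  meta <- intersect(
    c(
      "feature_id", "mean_mz", "adduct_label", "hmdb_accession",
      "metabolite_name", "adduct", "n_matches"
    ),
    names(df)
  )
  labs <- setdiff(names(df), meta)
  out <- structure(df,
    sample_labels = labs, polarity = polarity,
    class = c("feature_matrix", "data.frame")
  )
  out
}
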