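#' Pipeline configuration
#'
#' Collects and validates the pre-processing parameters. The tolerance is
#' deliberately a required argument with no default: it should equal the
#' external calibration range boundary of the instrument used (typically
#' 6 ppm for Orbitrap-class and 20 ppm for Q-TOF-class analyzers), a
#' property of the acquisition no software default can know. The
#' intensity cut-off defaults to 0 (keep every peak) and the sample
#' cut-off to 1 (drop features seen in a single sample) — the validated
#' defaults for FIA-HRMS matrices.
#'
#' @param tolerance_ppm matching tolerance t in ppm (> 0); used by blank
#'   subtraction, alignment, adduct grouping and annotation alike.
#' @param intensity_cutoff per-peak intensity threshold in AU (>= 0).
#' @param sample_cutoff feature-level detection threshold (integer >= 0).
#' @param polarity ionization mode of the batch.
#' @param sort_by_adducts regroup the aligned matrix into
#'   M+H/M+Na/M+K groups; positive mode only.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tolerance_ppm,
                            intensity_cutoff = 0,
                            sample_cutoff = 1L,
                            polarity = c("positive", "negative"),
                            sort_by_adducts = FALSE) {
  polarity <- match.arg(polarity)
  if (missing(tolerance_ppm) || !is.numeric(tolerance_ppm) || tolerance_ppm <= 0) {
    stop("tolerance_ppm is required and must be > 0", call. = FALSE)
  }
  if (intensity_cutoff < 0) stop("intensity_cutoff must be >= 0", call. = FALSE)
  if (sample_cutoff < 0) stop("sample_cutoff must be >= 0", call. = FALSE)
  if (isTRUE(sort_by_adducts) && polarity != "positive") {
    stop("sort_by_adducts is available for the positive ionization mode only", call. = FALSE)
  }
  structure(
    list(
      tolerance_ppm = tolerance_ppm, intensity_cutoff = intensity_cutoff,
      sample_cutoff = as.integer(sample_cutoff), polarity = polarity,
      sort_by_adducts = isTRUE(sort_by_adducts)
    ),
    class = "pipeline_config"
  )
}

#' Run the full pre-processing pipeline
#'
#' Orchestrates the three stages end to end: per-pair blank subtraction
#' (with optional intensity cut-off), cross-sample alignment into a
#' feature matrix (zeros cleaned to missing, sample cut-off applied),
#' optional adduct regrouping, and optional database annotation. All
#' artifacts are written with the conventional suffixes
#' (`_alignment_data`, `_alignment_data_sorted`, `_HMDB_ID`).
#'
#' @param batch an [acquisition_batch()], or a path to a manifest CSV
#'   (read with [read_manifest()]).
#' @param config a [pipeline_config()].
#' @param db an `adduct_database` for annotation, or `NULL` to skip it.
#' @param out_dir output directory.
#' @param basename base name for output files.
#' @param quiet suppress per-stage progress messages.
#' @return A `fia_run_report`: per-stage counts (peaks in/out of blank
#'   subtraction and cut-off per sample, features before/after the
#'   sample cut-off, annotation tallies), the parameters used, the file
#'   paths written, and the final matrix under `$matrix`.
#' @export
run_pipeline <- function(batch, config, db = NULL, out_dir = ".",
                         basename = "fiaprep", quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(batch)) batch <- read_manifest(batch, polarity = config$polarity)
  stopifnot(inherits(batch, "acquisition_batch"))
  if (!identical(batch$polarity, config$polarity)) {
    stop("batch polarity does not match the configuration", call. = FALSE)
  }
  if (!is.null(db) && !identical(attr(db, "polarity"), config$polarity)) {
    stop("database polarity does not match the configuration", call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  labels <- batch_labels(batch)
  n <- length(batch$pairs)
  peaks_in <- peaks_after_blank <- peaks_after_cutoff <- integer(n)
  subtracted <- vector("list", n)
  for (i in seq_len(n)) {
    p <- batch$pairs[[i]]
    peaks_in[i] <- nrow(p$sample)
    sub <- subtract_blank(p$sample, p$blank, config$tolerance_ppm)
    peaks_after_blank[i] <- nrow(sub$spectrum)
    cut <- apply_intensity_cutoff(sub$spectrum, config$intensity_cutoff)
    peaks_after_cutoff[i] <- nrow(cut)
    subtracted[[i]] <- cut
  }
  say(
    "blank subtraction: %d peaks in, %d out (%d removed) across %d samples",
    sum(peaks_in), sum(peaks_after_cutoff),
    sum(peaks_in) - sum(peaks_after_cutoff), n
  )

  matrix <- align_features(subtracted, config$tolerance_ppm)
  matrix <- clean_matrix(matrix)
  features_aligned <- nrow(matrix)
  matrix <- apply_sample_cutoff(matrix, config$sample_cutoff)
  features_kept <- nrow(matrix)
  say(
    "alignment: %d features, %d kept after sample cut-off %d",
    features_aligned, features_kept, config$sample_cutoff
  )

  files <- character(0)
  groups <- NULL
  if (config$sort_by_adducts) {
    sorted <- sort_matrix_by_adducts(matrix, config$tolerance_ppm)
    matrix <- sorted$matrix
    groups <- sorted$groups
    say("adduct grouping: %d non-empty groups", nrow(groups))
  }
  files <- c(files, write_matrix(
    matrix, file.path(out_dir, basename),
    sorted_by_adducts = config$sort_by_adducts
  ))

  annotation <- list(run = FALSE, n_single = NA_integer_, n_ambiguous = NA_integer_, n_unmatched = NA_integer_)
  if (!is.null(db)) {
    matrix <- annotate_matrix(matrix, db, config$tolerance_ppm)
    annotation <- list(
      run = TRUE,
      n_single = sum(matrix$n_matches == 1L),
      n_ambiguous = sum(matrix$n_matches > 1L),
      n_unmatched = sum(matrix$n_matches == 0L)
    )
    files <- c(files, write_matrix(matrix, file.path(out_dir, basename)))
    audit_path <- file.path(out_dir, paste0(basename, "_HMDB_ID_candidates.csv"))
    utils::write.csv(attr(matrix, "match_audit"), audit_path, row.names = FALSE)
    files <- c(files, audit_path)
    say(
      "annotation: %d single-match, %d ambiguous, %d unmatched features",
      annotation$n_single, annotation$n_ambiguous, annotation$n_unmatched
    )
  } else {
    say("annotation: not run (no database supplied)")
  }

  report <- structure(
    list(
      parameters = unclass(config),
      samples = data.frame(
        label = labels, peaks_in = peaks_in,
        peaks_after_blank = peaks_after_blank,
        peaks_after_cutoff = peaks_after_cutoff,
        stringsAsFactors = FALSE
      ),
      features_aligned = features_aligned,
      features_after_sample_cutoff = features_kept,
      features_removed_by_sample_cutoff = features_aligned - features_kept,
      adduct_groups = groups,
      annotation = annotation,
      files = files,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      matrix = matrix
    ),
    class = "fia_run_report"
  )
  report
}

#' @export
print.fia_run_report <- function(x, ...) {
  p <- x$parameters
  cat("FIA-HRMS pre-processing run\n")
  cat(sprintf(
    "  parameters: t = %g ppm, intensity cutoff %g, sample cutoff %d, %s mode%s\n",
    p$tolerance_ppm, p$intensity_cutoff, p$sample_cutoff, p$polarity,
    if (p$sort_by_adducts) ", adduct-sorted" else ""
  ))
  cat(sprintf(
    "  blank subtraction: %d peaks in -> %d out across %d samples\n",
    sum(x$samples$peaks_in), sum(x$samples$peaks_after_cutoff), nrow(x$samples)
  ))
  cat(sprintf(
    "  alignment: %d features aligned, %d kept after sample cut-off\n",
    x$features_aligned, x$features_after_sample_cutoff
  ))
  if (isTRUE(x$annotation$run)) {
    cat(sprintf(
      "  annotation: %d single-match, %d ambiguous, %d unmatched\n",
      x$annotation$n_single, x$annotation$n_ambiguous, x$annotation$n_unmatched
    ))
  } else {
    cat("  annotation: not run\n")
  }
  cat("  files:", paste(x$files, collapse = ", "), "\n")
  invisible(x)
}
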