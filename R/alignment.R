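#' Align peaks across samples into a feature matrix
#'
#' Greedy cross-sample m/z alignment with a progressively updated mean.
#' Every peak of the first sample seeds a feature whose running mean m/z
#' starts at that peak. For each subsequent sample, features are visited
#' in ascending running-mean order and each claims its closest unassigned
#' peak (in ppm, against the current running mean, within the tolerance);
#' the mean is updated immediately after each accepted member, so later
#' comparisons see the drifted mean. Peaks of that sample left unassigned
#' then seed new features. Every input peak therefore lands in exactly one
#' feature, and each feature holds at most one peak per sample.
#'
#' Ties at equal ppm distance are broken toward the lower m/z. The running
#' mean is the ppm denominator throughout.
#'
#' @param spectra list of blank-subtracted [centroid_spectrum()] objects,
#'   one per sample, in acquisition order; or an [acquisition_batch()]
#'   (its sample spectra are used as-is).
#' @param tolerance_ppm matching tolerance t in ppm (> 0).
#' @return A [feature_matrix()]: rows sorted by ascending mean m/z,
#'   sequential 1-based `feature_id`, one intensity column per sample with
#'   `NA` where the feature was not detected.
#' @export
align_features <- function(spectra, tolerance_ppm) {
  if (inherits(spectra, "acquisition_batch")) {
    spectra <- lapply(spectra$pairs, `[[`, "sample")
  }
  if (length(spectra) == 0L) stop("empty batch: no spectra to align", call. = FALSE)
  stopifnot(all(vapply(spectra, inherits, logical(1L), "centroid_spectrum")))
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0", call. = FALSE)

  n_samples <- length(spectra)
  labels <- vapply(spectra, spectrum_label, character(1L))
  polarity <- spectrum_polarity(spectra[[1L]])

  # Feature state: running sums and member lists, grown as peaks seed
  # new features. Kept as flat vectors for speed at matrix scale.
  f_sum <- numeric(0) # sum of member m/z
  f_n <- integer(0) # member count
  members <- list() # per feature: data.frame(sample, mz, intensity)

  seed_from <- function(spec, s) {
    k <- nrow(spec)
    if (k == 0L) {
      return(invisible())
    }
    f_sum <<- c(f_sum, spec$mz)
    f_n <<- c(f_n, rep(1L, k))
    members <<- c(members, lapply(seq_len(k), function(i) {
      list(list(sample = s, mz = spec$mz[i], intensity = spec$intensity[i]))
    }))
  }

  seed_from(spectra[[1L]], 1L)
  for (s in seq_len(n_samples)[-1L]) {
    spec <- spectra[[s]]
    unassigned <- rep(TRUE, nrow(spec))
    for (f in order(f_sum / f_n)) {
      mean_f <- f_sum[f] / f_n[f]
      idx <- ppm_window(mean_f, spec$mz, tolerance_ppm)
      idx <- idx[unassigned[idx]]
      if (length(idx) == 0L) next
      d <- ppm_delta(spec$mz[idx], mean_f)
      best <- idx[order(d, spec$mz[idx])[1L]]
      unassigned[best] <- FALSE
      f_sum[f] <- f_sum[f] + spec$mz[best]
      f_n[f] <- f_n[f] + 1L
      members[[f]] <- c(members[[f]], list(
        list(sample = s, mz = spec$mz[best], intensity = spec$intensity[best])
      ))
    }
    if (any(unassigned)) {
      seed_from(spec[unassigned, , drop = FALSE], s)
    }
  }

  mean_mz <- f_sum / f_n
  ord <- order(mean_mz)
  intensities <- matrix(NA_real_, nrow = length(ord), ncol = n_samples)
  for (r in seq_along(ord)) {
    for (m in members[[ord[r]]]) {
      intensities[r, m$sample] <- m$intensity
    }
  }
  feature_matrix(
    feature_id = seq_along(ord), mean_mz = mean_mz[ord],
    intensities = intensities, sample_labels = labels, polarity = polarity
  )
}

#' Replace zero intensities with missing markers
#'
#' Matrix cleaning: any stored intensity equal to 0 becomes the missing
#' marker `NA`, so the absence of signal and a literal zero reading are
#' treated identically by downstream filtering and statistics.
#'
#' @param matrix a [feature_matrix()].
#' @return The cleaned `feature_matrix`; all non-zero values unchanged.
#' @export
clean_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "feature_matrix"))
  for (col in intensity_columns(matrix)) {
    v <- matrix[[col]]
    v[!is.na(v) & v == 0] <- NA_real_
    matrix[[col]] <- v
  }
  matrix
}

#' Remove features detected in too few samples
#'
#' Drops every feature whose number of non-missing intensities is less
#' than or equal to the cut-off. The default of 1 removes exactly the
#' features detected in a single sample, the main source of matrix bloat
#' in FIA-HRMS tables. Feature identifiers are deliberately not renumbered
#' so surviving rows stay traceable to the pre-filter matrix.
#'
#' @param matrix a [feature_matrix()].
#' @param cutoff integer >= 0; features detected in `<= cutoff` samples
#'   are removed. 0 is the identity.
#' @return The filtered `feature_matrix`.
#' @export
apply_sample_cutoff <- function(matrix, cutoff = 1L) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (cutoff < 0) stop("sample cutoff must be >= 0", call. = FALSE)
  if (cutoff == 0) {
    return(matrix)
  }
  cols <- intensity_columns(matrix)
  detected <- rowSums(!is.na(as.matrix(matrix[, cols, drop = FALSE])))
  out <- matrix[detected > cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}
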