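#' Relative mass difference in parts per million
#'
#' The ppm distance between an observed mass and a reference mass,
#' `|mz_a - mz_b| / mz_b * 1e6`. The second argument is always the
#' reference (the blank peak during blank subtraction, the theoretical
#' database mass during annotation); at the tolerances used in FIA-HRMS
#' (<= 20 ppm) the choice of denominator is immaterial to first order but
#' it is fixed so results are bit-reproducible.
#'
#' @param mz_a observed mass(es), Th.
#' @param mz_b reference mass(es), Th. Recycled against `mz_a`.
#' @return Non-negative ppm distance(s).
#' @examples
#' ppm_delta(100.0005, 100.0000) # 5
#' @export
ppm_delta <- function(mz_a, mz_b) {
  if (any(mz_a <= 0) || any(mz_b <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  abs(mz_a - mz_b) / mz_b * 1e6
}

# Indices of reference masses within `tol_ppm` of `mz` (reference-mass
# denominator), assuming `ref` sorted ascending. Window bounds are widened
# slightly before the exact ppm filter so no boundary case is missed.
ppm_window <- function(mz, ref, tol_ppm) {
  tau <- tol_ppm * 1e-6
  lo <- findInterval(mz * (1 - 2 * tau), ref) + 1L
  hi <- findInterval(mz * (1 + 2 * tau), ref)
  if (lo > hi) {
    return(integer(0))
  }
  idx <- lo:hi
  idx[ppm_delta(mz, ref[idx]) <= tol_ppm]
}

#' Subtract the paired blank from a sample spectrum
#'
#' For each sample peak, all blank peaks within the ppm tolerance are
#' collected; if any match, the intensity of the single closest blank peak
#' (smallest ppm distance; ties broken toward the lower m/z) is subtracted
#' once from the sample peak. Results that reach zero or below are removed
#' from the spectrum. Unmatched sample peaks pass through unchanged, and a
#' blank peak may serve several sample peaks since sample peaks are
#' processed independently.
#'
#' @param sample a [centroid_spectrum()] of the sample acquisition.
#' @param blank a [centroid_spectrum()] of the paired blank, same polarity.
#' @param tolerance_ppm matching tolerance t in ppm (> 0); the blank peak
#'   m/z is the ppm denominator.
#' @return A list with
#'   \describe{
#'     \item{spectrum}{the blank-subtracted `centroid_spectrum`;}
#'     \item{matches}{audit table of every candidate match: columns
#'       `sample_mz`, `blank_mz`, `ppm`, `selected` (logical), one row per
#'       sample-peak/blank-peak candidate pair within tolerance.}
#'   }
#' @export
subtract_blank <- function(sample, blank, tolerance_ppm) {
  stopifnot(inherits(sample, "centroid_spectrum"), inherits(blank, "centroid_spectrum"))
  if (!identical(spectrum_polarity(sample), spectrum_polarity(blank))) {
    stop("sample and blank polarities differ", call. = FALSE)
  }
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0", call. = FALSE)

  n <- nrow(sample)
  out_int <- sample$intensity
  rec_sample <- rec_blank <- rec_ppm <- vector("list", n)
  rec_sel <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- ppm_window(sample$mz[i], blank$mz, tolerance_ppm)
    if (length(idx) == 0L) next
    d <- ppm_delta(sample$mz[i], blank$mz[idx])
    best <- idx[order(d, blank$mz[idx])[1L]]
    out_int[i] <- max(0, sample$intensity[i] - blank$intensity[best])
    rec_sample[[i]] <- rep(sample$mz[i], length(idx))
    rec_blank[[i]] <- blank$mz[idx]
    rec_ppm[[i]] <- d
    rec_sel[[i]] <- idx == best
  }
  keep <- out_int > 0
  spectrum <- centroid_spectrum(
    sample$mz[keep], out_int[keep],
    label = spectrum_label(sample), polarity = spectrum_polarity(sample)
  )
  matches <- data.frame(
    sample_mz = unlist(rec_sample), blank_mz = unlist(rec_blank),
    ppm = unlist(rec_ppm), selected = unlist(rec_sel)
  )
  if (nrow(matches) == 0L) {
    matches <- data.frame(
      sample_mz = numeric(0), blank_mz = numeric(0),
      ppm = numeric(0), selected = logical(0)
    )
  }
  list(spectrum = spectrum, matches = matches)
}

#' Discard peaks below an intensity cut-off
#'
#' Removes peaks with intensity strictly below the cut-off. The default
#' cut-off of 0 keeps every peak (identity), which is the recommended
#' setting: FIA-HRMS intensities span several orders of magnitude and
#' blank/sample intensity distributions overlap, so any fixed threshold
#' is an arbitrary choice left to the user.
#'
#' @param spectrum a [centroid_spectrum()].
#' @param cutoff intensity threshold in AU (>= 0); peaks with
#'   `intensity < cutoff` are removed.
#' @return The filtered `centroid_spectrum`.
#' @export
apply_intensity_cutoff <- function(spectrum, cutoff = 0) {
  stopifnot(inherits(spectrum, "centroid_spectrum"))
  if (cutoff < 0) stop("intensity cutoff must be >= 0", call. = FALSE)
  if (cutoff == 0) {
    return(spectrum)
  }
  keep <- spectrum$intensity >= cutoff
  centroid_spectrum(
    spectrum$mz[keep], spectrum$intensity[keep],
    label = spectrum_label(spectrum), polarity = spectrum_polarity(spectrum)
  )
}
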