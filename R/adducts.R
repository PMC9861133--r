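#' Ion mass constants
#'
#' Masses (u) of the charge-carrying species used in adduct arithmetic.
#' The proton is the carrier of [M+H]+ ionization, so the neutral mass of
#' a singly charged [M+H]+ ion is `mz - proton`; the sodium and potassium
#' entries are the cation masses (atomic mass minus one electron), since
#' the species attached to M in [M+Na]+/[M+K]+ is the cation. The neutral
#' hydrogen-atom and electron masses are exposed so the alternative
#' convention (subtracting atomic H, a 0.000549 u difference that is
#' material at 6 ppm near m/z 150) remains reproducible.
#'
#' @return Named list: `proton`, `sodium`, `potassium`, `hydrogen_atom`,
#'   `electron`, all in u.
#' @references CODATA/NIST atomic mass tables.
#' @export
ion_masses <- function() {
  list(
    proton = 1.00727646688,
    sodium = 22.98922070, # 22.98976928 (Na) - electron
    potassium = 38.96315791, # 38.96370649 (K)  - electron
    hydrogen_atom = 1.00782503207,
    electron = 0.00054857991
  )
}

#' Neutral monoisotopic mass from an [M+H]+ m/z
#'
#' Subtracts the proton mass under the singly charged assumption.
#'
#' @param mz observed m/z, must exceed the proton mass.
#' @return Neutral mass M in u.
#' @examples
#' compute_neutral_mass(181.070666) # glucose [M+H]+ -> 180.06339
#' @export
compute_neutral_mass <- function(mz) {
  proton <- ion_masses()$proton
  if (any(mz <= proton)) {
    stop("m/z must exceed the proton mass", call. = FALSE)
  }
  mz - proton
}

#' Theoretical sodium and potassium adduct m/z values
#'
#' @param neutral_mass neutral monoisotopic mass M in u (> 0).
#' @return Named numeric vector `c(mz_na =, mz_k =)` of the [M+Na]+ and
#'   [M+K]+ m/z values.
#' @export
theoretical_adducts <- function(neutral_mass) {
  if (any(neutral_mass <= 0)) stop("neutral mass must be positive", call. = FALSE)
  im <- ion_masses()
  c(mz_na = neutral_mass + im$sodium, mz_k = neutral_mass + im$potassium)
}

#' Regroup matrix rows into M+H / M+Na / M+K adduct groups
#'
#' Positive-mode only. Every row, visited in ascending mean m/z, is
#' treated as a candidate [M+H]+ anchor: the proton mass is subtracted to
#' obtain a putative neutral mass, the theoretical [M+Na]+ and [M+K]+ m/z
#' are computed, and the not-yet-regrouped rows are searched for matches
#' within the ppm tolerance (theoretical m/z as denominator; closest ppm
#' wins when several rows qualify). Matched rows are relocated directly
#' beneath their anchor and labelled in a dedicated `adduct_label` column;
#' a row claimed as an adduct is skipped when its turn as an anchor comes.
#' Rows are only permuted and labelled, never duplicated or lost.
#'
#' @param matrix a positive-mode [feature_matrix()].
#' @param tolerance_ppm matching tolerance t in ppm (> 0).
#' @return A list with
#'   \describe{
#'     \item{matrix}{the regrouped `feature_matrix` with an
#'       `adduct_label` column (`"M+H"`, `"M+Na"`, `"M+K"`, or `""`);}
#'     \item{groups}{data frame of non-empty groups: columns
#'       `anchor_feature_id`, `sodium_feature_id`, `potassium_feature_id`
#'       (`NA` when unobserved), `neutral_mass`.}
#'   }
#' @export
sort_matrix_by_adducts <- function(matrix, tolerance_ppm) {
  stopifnot(inherits(matrix, "feature_matrix"))
  if (!identical(matrix_polarity(matrix), "positive")) {
    stop("adduct grouping is available for the positive ionization mode only", call. = FALSE)
  }
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0", call. = FALSE)

  ord <- order(matrix$mean_mz)
  mz <- matrix$mean_mz[ord] # ascending
  n <- length(mz)
  claimed <- rep(FALSE, n) # claimed as somebody's Na/K adduct
  label <- rep("", n)
  im <- ion_masses()

  # For each candidate target mass, the closest unclaimed row within t.
  find_partner <- function(target, self) {
    idx <- ppm_window(target, mz, tolerance_ppm)
    idx <- idx[!claimed[idx] & idx != self]
    if (length(idx) == 0L) {
      return(NA_integer_)
    }
    d <- ppm_delta(mz[idx], target)
    idx[order(d, mz[idx])[1L]]
  }

  groups <- list()
  out_order <- integer(0)
  for (i in seq_len(n)) {
    if (claimed[i]) next
    if (mz[i] <= im$proton) {
      out_order <- c(out_order, i)
      next
    }
    neutral <- mz[i] - im$proton
    targets <- theoretical_adducts(neutral)
    na_row <- find_partner(targets[["mz_na"]], i)
    k_row <- find_partner(targets[["mz_k"]], i)
    out_order <- c(out_order, i)
    if (!is.na(na_row) || !is.na(k_row)) {
      label[i] <- "M+H"
      if (!is.na(na_row)) {
        claimed[na_row] <- TRUE
        label[na_row] <- "M+Na"
        out_order <- c(out_order, na_row)
      }
      if (!is.na(k_row)) {
        claimed[k_row] <- TRUE
        label[k_row] <- "M+K"
        out_order <- c(out_order, k_row)
      }
      groups[[length(groups) + 1L]] <- data.frame(
        anchor_feature_id = matrix$feature_id[ord[i]],
        sodium_feature_id = if (is.na(na_row)) NA_integer_ else matrix$feature_id[ord[na_row]],
        potassium_feature_id = if (is.na(k_row)) NA_integer_ else matrix$feature_id[ord[k_row]],
        neutral_mass = neutral
      )
    }
  }

  perm <- ord[out_order]
  out <- matrix[perm, , drop = FALSE]
  out$adduct_label <- label[out_order]
  rownames(out) <- NULL
  groups <- if (length(groups)) {
    do.call(rbind, groups)
  } else {
    data.frame(
      anchor_feature_id = integer(0), sodium_feature_id = integer(0),
      potassium_feature_id = integer(0), neutral_mass = numeric(0)
    )
  }
  list(matrix = out, groups = groups)
}
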