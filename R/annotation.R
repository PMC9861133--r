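#' Build an adduct-mass database from HMDB-style metabolite XML
#'
#' Parses an XML dump of metabolite records (accession, name,
#' monoisotopic mass) and expands each metabolite into its theoretical
#' adduct m/z values for one polarity: `M + proton`, `M + Na+`, `M + K+`
#' in positive mode, `M - proton` in negative mode, using the same
#' [ion_masses()] constants as adduct grouping. Metabolites with a
#' missing, non-numeric or non-positive monoisotopic mass are skipped and
#' counted. Tag names default to the HMDB conventions (including HMDB's
#' historical spelling `monisotopic_molecular_weight`) but are
#' configurable for other XML schemas.
#'
#' @param xml_path path to the XML file.
#' @param polarity ionization mode of the database to build.
#' @param metabolite_tag,accession_tag,name_tag,mass_tag element names in
#'   the XML schema.
#' @return An `adduct_database`: a data frame with columns
#'   `theoretical_mz`, `adduct`, `accession`, `name`,
#'   `monoisotopic_mass`, sorted by `theoretical_mz`; attributes
#'   `polarity` and `n_skipped`.
#' @export
build_adduct_database <- function(xml_path,
                                  polarity = c("positive", "negative"),
                                  metabolite_tag = "metabolite",
                                  accession_tag = "accession",
                                  name_tag = "name",
                                  mass_tag = "monisotopic_molecular_weight") {
  polarity <- match.arg(polarity)
  if (!file.exists(xml_path)) {
    stop(sprintf("XML file not found: '%s'", xml_path), call. = FALSE)
  }
  doc <- tryCatch(xml2::read_xml(xml_path), error = function(e) {
    stop(sprintf("malformed XML in '%s': %s", xml_path, conditionMessage(e)), call. = FALSE)
  })
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, paste0("//", metabolite_tag))
  if (length(nodes) == 0L) {
    stop("no metabolite elements found in XML", call. = FALSE)
  }
  field <- function(node, tag) {
    v <- xml2::xml_find_first(node, paste0("./", tag))
    if (inherits(v, "xml_missing")) NA_character_ else xml2::xml_text(v)
  }
  accession <- vapply(nodes, field, character(1L), accession_tag)
  name <- vapply(nodes, field, character(1L), name_tag)
  mass <- suppressWarnings(as.numeric(vapply(nodes, field, character(1L), mass_tag)))
  usable <- !is.na(accession) & !is.na(mass) & mass > 0
  n_skipped <- sum(!usable)
  if (!any(usable)) stop("zero usable metabolites in XML", call. = FALSE)
  records <- data.frame(
    accession = accession[usable], name = name[usable],
    monoisotopic_mass = mass[usable], stringsAsFactors = FALSE
  )
  adduct_database_from_records(records, polarity, n_skipped = n_skipped)
}

#' Build an adduct-mass database from an in-memory record table
#'
#' Same expansion as [build_adduct_database()] but starting from a data
#' frame of metabolite records, e.g. the ground-truth table of
#' [simulate_batch()] or a cached database CSV.
#'
#' @param records data frame with columns `accession`, `name`,
#'   `monoisotopic_mass`.
#' @param polarity ionization mode.
#' @param n_skipped skip count carried over from parsing (metadata only).
#' @return An `adduct_database` (see [build_adduct_database()]).
#' @export
adduct_database_from_records <- function(records, polarity = c("positive", "negative"),
                                         n_skipped = 0L) {
  polarity <- match.arg(polarity)
  stopifnot(all(c("accession", "name", "monoisotopic_mass") %in% names(records)))
  if (anyDuplicated(records$accession)) {
    stop("duplicate accession in metabolite records", call. = FALSE)
  }
  if (any(records$monoisotopic_mass <= 0)) {
    stop("monoisotopic masses must be positive", call. = FALSE)
  }
  im <- ion_masses()
  expand <- function(adduct, delta) {
    data.frame(
      theoretical_mz = records$monoisotopic_mass + delta,
      adduct = adduct, accession = records$accession, name = records$name,
      monoisotopic_mass = records$monoisotopic_mass, stringsAsFactors = FALSE
    )
  }
  db <- if (polarity == "positive") {
    rbind(
      expand("M+H", im$proton),
      expand("M+Na", im$sodium),
      expand("M+K", im$potassium)
    )
  } else {
    expand("M-H", -im$proton)
  }
  db <- db[order(db$theoretical_mz, db$accession, db$adduct), , drop = FALSE]
  rownames(db) <- NULL
  structure(db,
    polarity = polarity, n_skipped = as.integer(n_skipped),
    class = c("adduct_database", "data.frame")
  )
}

#' @export
print.adduct_database <- function(x, ...) {
  cat(sprintf(
    "Adduct database (%s mode): %d entries, %d metabolites (%d records skipped)\n",
    attr(x, "polarity"), nrow(x), length(unique(x$accession)), attr(x, "n_skipped")
  ))
  invisible(x)
}

#' Write / read a cached adduct database CSV
#'
#' The sorted database table round-trips through a plain CSV so an
#' expensive XML parse can be done once and reused.
#'
#' @param db an `adduct_database`.
#' @param path CSV path.
#' @return `write_adduct_database` returns `path` invisibly;
#'   `read_adduct_database` returns the `adduct_database`.
#' @export
write_adduct_database <- function(db, path) {
  stopifnot(inherits(db, "adduct_database"))
  utils::write.csv(as.data.frame(db), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_adduct_database
#' @param polarity ionization mode of the cached table.
#' @export
read_adduct_database <- function(path, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (!file.exists(path)) stop(sprintf("database CSV not found: '%s'", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("theoretical_mz", "adduct", "accession", "name", "monoisotopic_mass")
  if (!all(req %in% names(df))) {
    stop("database CSV must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  df <- df[order(df$theoretical_mz, df$accession, df$adduct), req, drop = FALSE]
  rownames(df) <- NULL
  structure(df,
    polarity = polarity, n_skipped = 0L,
    class = c("adduct_database", "data.frame")
  )
}

#' Annotate matrix features against an adduct-mass database
#'
#' For each feature, all database entries whose theoretical m/z lies
#' within the ppm tolerance of the feature's mean m/z are collected
#' (theoretical m/z is the ppm denominator; the sorted table is searched
#' by interval lookup, keeping each query sub-linear). Features with
#' exactly one match receive the accession, metabolite name and adduct;
#' ambiguous features carry only the match count; unmatched features pass
#' through unannotated. Mean m/z, intensities and row count are never
#' altered. The full candidate list of every feature with at least one
#' match is attached as an audit table.
#'
#' @param matrix a [feature_matrix()] (or one re-read from CSV with
#'   [read_matrix_csv()]).
#' @param db an `adduct_database` of the same polarity.
#' @param tolerance_ppm matching tolerance t in ppm (> 0).
#' @return An `annotated_matrix`: the input matrix plus columns
#'   `hmdb_accession`, `metabolite_name`, `adduct` (filled only for
#'   single matches) and `n_matches`; attribute `match_audit` holds the
#'   full candidate table (columns `feature_id`, `mean_mz`,
#'   `theoretical_mz`, `ppm`, `accession`, `name`, `adduct`).
#' @export
annotate_matrix <- function(matrix, db, tolerance_ppm) {
  stopifnot(inherits(matrix, "feature_matrix"), inherits(db, "adduct_database"))
  if (!identical(matrix_polarity(matrix), attr(db, "polarity"))) {
    stop("matrix and database polarities differ", call. = FALSE)
  }
  if (tolerance_ppm <= 0) stop("tolerance_ppm must be > 0", call. = FALSE)

  n <- nrow(matrix)
  accession <- name <- adduct <- rep(NA_character_, n)
  n_matches <- integer(n)
  audit <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- integer(0)
    if (nrow(db) > 0L) {
      idx <- ppm_window(matrix$mean_mz[i], db$theoretical_mz, tolerance_ppm)
    }
    n_matches[i] <- length(idx)
    if (length(idx) >= 1L) {
      audit[[i]] <- data.frame(
        feature_id = matrix$feature_id[i], mean_mz = matrix$mean_mz[i],
        theoretical_mz = db$theoretical_mz[idx],
        ppm = ppm_delta(matrix$mean_mz[i], db$theoretical_mz[idx]),
        accession = db$accession[idx], name = db$name[idx],
        adduct = db$adduct[idx], stringsAsFactors = FALSE
      )
    }
    if (length(idx) == 1L) {
      accession[i] <- db$accession[idx]
      name[i] <- db$name[idx]
      adduct[i] <- db$adduct[idx]
    }
  }
  out <- matrix
  out$hmdb_accession <- accession
  out$metabolite_name <- name
  out$adduct <- adduct
  out$n_matches <- n_matches
  audit <- audit[!vapply(audit, is.null, logical(1L))]
  audit <- if (length(audit)) {
    do.call(rbind, audit)
  } else {
    data.frame(
      feature_id = integer(0), mean_mz = numeric(0), theoretical_mz = numeric(0),
      ppm = numeric(0), accession = character(0), name = character(0),
      adduct = character(0), stringsAsFactors = FALSE
    )
  }
  rownames(audit) <- NULL
  attr(out, "match_audit") <- audit
  class(out) <- c("annotated_matrix", class(matrix))
  out
}
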