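#' Specification for a synthetic acquisition batch
#'
#' Defines the ground-truth structure of a simulated FIA-HRMS batch:
#' planted m/z features with ppm-scale mass jitter, per-sample detection
#' dropout, carrier-solvent contaminants planted in both blank and
#' sample, and an optional fraction of features emitted as full
#' [M+H]+/[M+Na]+/[M+K]+ adduct triplets with a consistent neutral mass.
#'
#' Defaults emulate a small Orbitrap-class plasma batch: m/z 80-1000
#' (instruments in this regime record roughly 50-1000), lognormal
#' intensities whose heavy tail spans several orders of magnitude,
#' sub-ppm mass jitter (so that 3 sigma stays well inside half of a 6 ppm
#' tolerance window), and feature centers kept at least 50 ppm apart so
#' planted features are unambiguous at any tolerance up to ~12 ppm.
#'
#' @param n_samples number of sample acquisitions.
#' @param n_features number of planted features ([M+H]+ anchors).
#' @param mz_range numeric length-2, low/high m/z bounds (Th).
#' @param jitter_sigma_ppm standard deviation of the multiplicative mass
#'   jitter, in ppm.
#' @param detection_prob probability that a feature is detected in a
#'   given sample.
#' @param n_contaminants number of solvent contaminant species.
#' @param contaminant_lognormal `c(meanlog, sdlog)` of contaminant
#'   intensities (AU).
#' @param contaminant_intensity_mismatch multiplier applied to the
#'   contaminant intensity in the sample relative to the blank; 1 (the
#'   default) plants equal intensities so simple subtraction removes the
#'   contaminant exactly.
#' @param triplet_fraction fraction of features emitted as full adduct
#'   triplets.
#' @param intensity_lognormal `c(meanlog, sdlog)` of feature intensities
#'   (AU).
#' @param min_separation_ppm minimum pairwise separation of all planted
#'   m/z centers (features, their adducts, contaminants), in ppm.
#' @param seed integer RNG seed; the batch is deterministic given the
#'   spec.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_samples = 10L,
                            n_features = 60L,
                            mz_range = c(80, 1000),
                            jitter_sigma_ppm = 0.8,
                            detection_prob = 0.8,
                            n_contaminants = 20L,
                            contaminant_lognormal = c(8, 1.5),
                            contaminant_intensity_mismatch = 1,
                            triplet_fraction = 0.2,
                            intensity_lognormal = c(9, 2),
                            min_separation_ppm = 50,
                            seed = 1L) {
  spec <- list(
    n_samples = as.integer(n_samples), n_features = as.integer(n_features),
    mz_range = as.numeric(mz_range), jitter_sigma_ppm = jitter_sigma_ppm,
    detection_prob = detection_prob, n_contaminants = as.integer(n_contaminants),
    contaminant_lognormal = contaminant_lognormal,
    contaminant_intensity_mismatch = contaminant_intensity_mismatch,
    triplet_fraction = triplet_fraction,
    intensity_lognormal = intensity_lognormal,
    min_separation_ppm = min_separation_ppm, seed = as.integer(seed)
  )
  stopifnot(
    spec$n_samples >= 1L, spec$n_features >= 1L,
    length(spec$mz_range) == 2L, spec$mz_range[1L] > 0,
    spec$mz_range[2L] > spec$mz_range[1L],
    spec$jitter_sigma_ppm >= 0, spec$detection_prob >= 0, spec$detection_prob <= 1,
    spec$n_contaminants >= 0L, spec$triplet_fraction >= 0, spec$triplet_fraction <= 1,
    spec$min_separation_ppm > 0
  )
  structure(spec, class = "simulation_spec")
}

# Place n centers in [low, high] with pairwise separation > sep_ppm.
# Refuses infeasible requests instead of looping forever.
place_centers <- function(n, low, high, sep_ppm, max_tries = 200L) {
  if (n == 0L) {
    return(numeric(0))
  }
  capacity <- log(high / low) / (sep_ppm * 1e-6)
  if (n > 0.5 * capacity) {
    stop(sprintf(
      "infeasible simulation spec: %d centers cannot keep > %g ppm separation in m/z %g-%g (capacity ~%d)",
      n, sep_ppm, low, high, floor(0.5 * capacity)
    ), call. = FALSE)
  }
  for (try in seq_len(max_tries)) {
    centers <- sort(stats::runif(n, low, high))
    if (n == 1L || all(diff(centers) / centers[-n] * 1e6 > sep_ppm)) {
      return(centers)
    }
  }
  stop("infeasible simulation spec: could not place separated centers", call. = FALSE)
}

jitter_mz <- function(mz, sigma_ppm) {
  mz * (1 + stats::rnorm(length(mz), 0, sigma_ppm * 1e-6))
}

#' Simulate an acquisition batch with known ground truth
#'
#' Generates one blank per sample containing only the planted contaminant
#' peaks, and sample spectra containing the jittered feature peaks (each
#' present with the detection probability) plus the same contaminants,
#' independently re-jittered but with identical base intensity by
#' default. A fraction of features is emitted as adduct triplets whose
#' [M+Na]+/[M+K]+ peaks share the anchor's neutral mass. Every generated
#' peak is traceable to a ground-truth entry, so feature recovery,
#' contaminant removal, adduct grouping and annotation can all be scored
#' exactly.
#'
#' @param spec a [simulation_spec()].
#' @return A list with
#'   \describe{
#'     \item{batch}{an [acquisition_batch()] (positive mode);}
#'     \item{truth}{ground truth: `features` (center m/z, neutral mass,
#'       triplet flag, adduct centers, accession, name), `memberships`
#'       (one row per emitted feature/adduct peak per sample),
#'       `contaminants` (center m/z, base intensity), and `db_records`
#'       (a metabolite record per planted feature, usable with
#'       [adduct_database_from_records()]).}
#'   }
#' @export
simulate_batch <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  im <- ion_masses()

  n_triplets <- round(spec$triplet_fraction * spec$n_features)
  # Feature anchors ([M+H]+) and contaminants share one separation scheme;
  # triplet Na/K centers are offset from anchors by fixed mass differences,
  # so separating the anchor grid by sep + the largest ppm footprint of the
  # offsets is handled by joint placement of all emitted centers.
  n_centers_total <- spec$n_features + 2L * n_triplets + spec$n_contaminants
  # Place anchors and contaminants jointly, then verify Na/K centers too.
  for (attempt in seq_len(50L)) {
    base_centers <- place_centers(
      spec$n_features + spec$n_contaminants,
      spec$mz_range[1L], spec$mz_range[2L], spec$min_separation_ppm
    )
    pick <- sort(sample.int(spec$n_features + spec$n_contaminants, spec$n_features))
    feature_centers <- base_centers[pick]
    contaminant_centers <- base_centers[-pick]
    is_triplet <- rep(FALSE, spec$n_features)
    if (n_triplets > 0L) is_triplet[sample.int(spec$n_features, n_triplets)] <- TRUE
    neutral <- feature_centers - im$proton
    mz_na <- ifelse(is_triplet, neutral + im$sodium, NA_real_)
    mz_k <- ifelse(is_triplet, neutral + im$potassium, NA_real_)
    # Separation must hold for the theoretical Na/K masses of every
    # feature, planted or not: the annotation database carries those
    # entries, so a planted center sitting near any of them would make a
    # feature ambiguous by construction.
    all_centers <- sort(c(base_centers, neutral + im$sodium, neutral + im$potassium))
    sep_ok <- length(all_centers) < 2L ||
      all(diff(all_centers) / all_centers[-length(all_centers)] * 1e6 >
        spec$min_separation_ppm)
    if (sep_ok) break
    if (attempt == 50L) {
      stop("infeasible simulation spec: adduct centers collide with planted centers",
        call. = FALSE
      )
    }
  }

  features <- data.frame(
    feature = seq_len(spec$n_features),
    center_mz = feature_centers,
    neutral_mass = neutral,
    is_triplet = is_triplet,
    mz_na = mz_na, mz_k = mz_k,
    accession = sprintf("SYNDB%05d", seq_len(spec$n_features)),
    name = sprintf("synthetic metabolite %03d", seq_len(spec$n_features)),
    stringsAsFactors = FALSE
  )
  contaminants <- data.frame(
    contaminant = seq_len(spec$n_contaminants),
    center_mz = contaminant_centers,
    intensity = stats::rlnorm(
      spec$n_contaminants,
      spec$contaminant_lognormal[1L], spec$contaminant_lognormal[2L]
    )
  )

  pairs <- vector("list", spec$n_samples)
  memberships <- vector("list", spec$n_samples)
  for (s in seq_len(spec$n_samples)) {
    detected <- stats::runif(spec$n_features) <= spec$detection_prob
    det <- features[detected, , drop = FALSE]
    # one intensity draw per emitted peak (anchor, Na, K)
    emit <- data.frame(
      sample = rep(sprintf("sample_%02d", s), 0L),
      feature = integer(0), adduct = character(0),
      mz_true = numeric(0), stringsAsFactors = FALSE
    )
    if (nrow(det) > 0L) {
      emit <- rbind(
        data.frame(
          sample = sprintf("sample_%02d", s), feature = det$feature,
          adduct = "M+H", mz_true = det$center_mz, stringsAsFactors = FALSE
        ),
        if (any(det$is_triplet)) {
          tri <- det[det$is_triplet, , drop = FALSE]
          rbind(
            data.frame(
              sample = sprintf("sample_%02d", s), feature = tri$feature,
              adduct = "M+Na", mz_true = tri$mz_na, stringsAsFactors = FALSE
            ),
            data.frame(
              sample = sprintf("sample_%02d", s), feature = tri$feature,
              adduct = "M+K", mz_true = tri$mz_k, stringsAsFactors = FALSE
            )
          )
        }
      )
    }
    emit$mz_obs <- jitter_mz(emit$mz_true, spec$jitter_sigma_ppm)
    emit$intensity <- stats::rlnorm(
      nrow(emit),
      spec$intensity_lognormal[1L], spec$intensity_lognormal[2L]
    )
    memberships[[s]] <- emit

    cont_sample_mz <- jitter_mz(contaminants$center_mz, spec$jitter_sigma_ppm)
    cont_blank_mz <- jitter_mz(contaminants$center_mz, spec$jitter_sigma_ppm)
    sample_spec <- centroid_spectrum(
      c(emit$mz_obs, cont_sample_mz),
      c(emit$intensity, contaminants$intensity * spec$contaminant_intensity_mismatch),
      label = sprintf("sample_%02d", s), polarity = "positive"
    )
    blank_spec <- centroid_spectrum(
      cont_blank_mz, contaminants$intensity,
      label = sprintf("blank_%02d", s), polarity = "positive"
    )
    pairs[[s]] <- list(sample = sample_spec, blank = blank_spec)
  }

  truth <- list(
    features = features,
    memberships = do.call(rbind, memberships),
    contaminants = contaminants,
    db_records = data.frame(
      accession = features$accession, name = features$name,
      monoisotopic_mass = features$neutral_mass, stringsAsFactors = FALSE
    )
  )
  list(batch = acquisition_batch(pairs, polarity = "positive"), truth = truth)
}

#' Write a simulated batch as an on-disk fixture set
#'
#' Emits exactly the layout [read_manifest()] consumes — one CSV per
#' sample and per blank plus `manifest.csv` — together with the ground
#' truth tables (`truth_features.csv`, `truth_memberships.csv`,
#' `truth_contaminants.csv`, `truth_db.csv`) for assertions.
#'
#' @param batch an [acquisition_batch()].
#' @param truth the ground-truth list of [simulate_batch()], or `NULL`
#'   to write the spectra and manifest only.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_fixture_set <- function(batch, truth, dir) {
  stopifnot(inherits(batch, "acquisition_batch"))
  if (length(batch$pairs) == 0L) stop("empty batch", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  write_spectrum <- function(spec, path) {
    utils::write.csv(
      data.frame(mz = sprintf("%.6f", spec$mz), intensity = spec$intensity),
      path,
      row.names = FALSE, quote = FALSE
    )
  }
  rows <- vector("list", length(batch$pairs))
  for (i in seq_along(batch$pairs)) {
    p <- batch$pairs[[i]]
    sf <- sprintf("sample_%02d.csv", i)
    bf <- sprintf("blank_%02d.csv", i)
    write_spectrum(p$sample, file.path(dir, sf))
    write_spectrum(p$blank, file.path(dir, bf))
    rows[[i]] <- data.frame(
      sample_file = sf, blank_file = bf,
      label = spectrum_label(p$sample), stringsAsFactors = FALSE
    )
  }
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest_path, row.names = FALSE, quote = FALSE)
  if (!is.null(truth)) {
    utils::write.csv(truth$features, file.path(dir, "truth_features.csv"), row.names = FALSE)
    utils::write.csv(truth$memberships, file.path(dir, "truth_memberships.csv"), row.names = FALSE)
    utils::write.csv(truth$contaminants, file.path(dir, "truth_contaminants.csv"), row.names = FALSE)
    utils::write.csv(truth$db_records, file.path(dir, "truth_db.csv"), row.names = FALSE)
  }
  invisible(manifest_path)
}
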