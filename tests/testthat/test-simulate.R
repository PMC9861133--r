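test_that("simulation is deterministic under a fixed seed", {
  spec <- simulation_spec(n_samples = 5, n_features = 50, triplet_fraction = 0, seed = 7)
  a <- simulate_batch(spec)
  b <- simulate_batch(spec)
  for (i in seq_along(a$batch$pairs)) {
    expect_identical(a$batch$pairs[[i]]$sample$mz, b$batch$pairs[[i]]$sample$mz)
    expect_identical(a$batch$pairs[[i]]$sample$intensity, b$batch$pairs[[i]]$sample$intensity)
    expect_identical(a$batch$pairs[[i]]$blank$mz, b$batch$pairs[[i]]$blank$mz)
  }
  expect_identical(a$truth$features, b$truth$features)
})

test_that("peak counts follow the spec when detection is certain", {
  sim <- simulate_batch(simulation_spec(
    n_samples = 4, n_features = 25, detection_prob = 1,
    n_contaminants = 0, triplet_fraction = 0, seed = 3
  ))
  for (p in sim$batch$pairs) {
    expect_equal(nrow(p$sample), 25L)
    expect_equal(nrow(p$blank), 0L)
  }
})

test_that("blanks carry only contaminants; samples carry features plus contaminants", {
  sim <- simulate_batch(simulation_spec(
    n_samples = 3, n_features = 20, detection_prob = 1,
    n_contaminants = 8, triplet_fraction = 0, seed = 9
  ))
  for (p in sim$batch$pairs) {
    expect_equal(nrow(p$blank), 8L)
    expect_equal(nrow(p$sample), 28L)
    # blank m/z sit within jitter of planted contaminant centers
    d_ppm <- vapply(p$blank$mz, function(mz) {
      min(oracle_ppm(mz, sim$truth$contaminants$center_mz))
    }, 0)
    expect_true(all(d_ppm < 6))
  }
})

test_that("triplet fraction 1 emits three peaks per feature with ion-constant spacings", {
  sim <- simulate_batch(simulation_spec(
    n_samples = 2, n_features = 10, detection_prob = 1,
    n_contaminants = 0, triplet_fraction = 1, seed = 13
  ))
  im <- ion_masses()
  expect_true(all(sim$truth$features$is_triplet))
  for (p in sim$batch$pairs) {
    expect_equal(nrow(p$sample), 30L)
  }
  f <- sim$truth$features
  expect_equal(f$mz_na - f$center_mz, rep(im$sodium - im$proton, 10))
  expect_equal(f$mz_k - f$mz_na, rep(im$potassium - im$sodium, 10))
  # observed per-sample spacings match within jitter (< 0.01 u at these masses)
  mem <- sim$truth$memberships
  one <- mem[mem$sample == "sample_01" & mem$feature == f$feature[1], ]
  expect_equal(one$mz_obs[one$adduct == "M+Na"] - one$mz_obs[one$adduct == "M+H"],
    im$sodium - im$proton,
    tolerance = 0.01
  )
})

test_that("an infeasible center-separation request is refused with an explanation", {
  expect_error(
    simulate_batch(simulation_spec(
      n_features = 5000, mz_range = c(100, 110),
      min_separation_ppm = 100, seed = 1
    )),
    "infeasible"
  )
})

test_that("fixture sets round-trip through the manifest reader", {
  sim <- simulate_batch(simulation_spec(n_samples = 2, n_features = 15, seed = 21))
  dir <- tempfile()
  manifest <- write_fixture_set(sim$batch, sim$truth, dir)
  expect_setequal(
    list.files(dir),
    c(
      "sample_01.csv", "sample_02.csv", "blank_01.csv", "blank_02.csv",
      "manifest.csv", "truth_features.csv", "truth_memberships.csv",
      "truth_contaminants.csv", "truth_db.csv"
    )
  )
  batch <- read_manifest(manifest, polarity = "positive")
  expect_equal(length(batch$pairs), 2L)
  for (i in 1:2) {
    expect_equal(batch$pairs[[i]]$sample$mz, sim$batch$pairs[[i]]$sample$mz,
      tolerance = 1e-6
    )
    expect_equal(batch$pairs[[i]]$sample$intensity, sim$batch$pairs[[i]]$sample$intensity)
  }
})

test_that("lower detection probability yields fewer surviving features at cutoff 1", {
  survivors <- function(p, seed) {
    sim <- simulate_batch(simulation_spec(
      n_samples = 6, n_features = 40, detection_prob = p,
      n_contaminants = 0, triplet_fraction = 0, seed = seed
    ))
    spectra <- lapply(sim$batch$pairs, `[[`, "sample")
    m <- apply_sample_cutoff(clean_matrix(align_features(spectra, 6)), 1)
    nrow(m)
  }
  set.seed(77)
  hi <- mean(vapply(1:5, function(s) survivors(0.9, s), 0))
  lo <- mean(vapply(1:5, function(s) survivors(0.3, s), 0))
  expect_gt(hi, lo)
})
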