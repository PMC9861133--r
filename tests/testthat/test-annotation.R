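test_that("the positive database expands each metabolite into three adduct entries", {
  db <- build_adduct_database(fixture_xml(), "positive")
  glucose <- db[db$accession == "HMDB0000122", ]
  expect_equal(nrow(glucose), 3L)
  expect_equal(sort(glucose$adduct), c("M+H", "M+K", "M+Na"))
  expect_equal(glucose$theoretical_mz[glucose$adduct == "M+H"], 181.070666, tolerance = 1e-5)
  expect_equal(glucose$theoretical_mz[glucose$adduct == "M+Na"], 203.052608, tolerance = 1e-5)
  expect_equal(glucose$theoretical_mz[glucose$adduct == "M+K"], 219.026548, tolerance = 1e-5)
  # table sorted by theoretical m/z, three entries per usable metabolite
  expect_false(is.unsorted(db$theoretical_mz))
  expect_true(all(table(db$accession) == 3L))
})

test_that("the negative database holds one M-H entry per metabolite", {
  db <- build_adduct_database(fixture_xml(), "negative")
  expect_true(all(db$adduct == "M-H"))
  expect_equal(db$theoretical_mz[db$accession == "HMDB0000122"], 179.056114, tolerance = 1e-5)
  expect_true(all(table(db$accession) == 1L))
})

test_that("metabolites without a usable monoisotopic mass are skipped and counted", {
  db <- build_adduct_database(fixture_xml(), "positive")
  expect_equal(attr(db, "n_skipped"), 1L)
  expect_false("HMDB0003070" %in% db$accession)
})

test_that("database construction is deterministic and round-trips through CSV", {
  db1 <- build_adduct_database(fixture_xml(), "positive")
  db2 <- build_adduct_database(fixture_xml(), "positive")
  expect_identical(as.data.frame(db1), as.data.frame(db2))
  path <- tempfile(fileext = ".csv")
  write_adduct_database(db1, path)
  back <- read_adduct_database(path, "positive")
  expect_equal(back$theoretical_mz, db1$theoretical_mz)
  expect_equal(back$accession, db1$accession)
})

test_that("single, zero and ambiguous matches are annotated per the match count", {
  db <- build_adduct_database(fixture_xml(), "positive")
  m <- feature_matrix(1:2, c(181.070666, 500.000000),
    matrix(1, 2, 2), c("a", "b"),
    polarity = "positive"
  )
  ann <- annotate_matrix(m, db, 6)
  expect_equal(ann$n_matches, c(1L, 0L))
  expect_equal(ann$hmdb_accession[1], "HMDB0000122")
  expect_equal(ann$metabolite_name[1], "D-Glucose")
  expect_equal(ann$adduct[1], "M+H")
  expect_true(is.na(ann$hmdb_accession[2]))

  # two isobars 2 ppm apart, feature between them: count reported, no name
  iso <- adduct_database_from_records(
    data.frame(
      accession = c("A", "B"), name = c("a", "b"),
      monoisotopic_mass = c(400.0000, 400.0008)
    ),
    "positive"
  )
  m2 <- feature_matrix(1L, 400.0004 + ion_masses()$proton, matrix(1, 1, 1), "s",
    polarity = "positive"
  )
  ann2 <- annotate_matrix(m2, iso, 6)
  expect_equal(ann2$n_matches, 2L)
  expect_true(is.na(ann2$metabolite_name))
  expect_equal(nrow(attr(ann2, "match_audit")), 2L)
})

test_that("annotation equals a brute-force linear scan on random databases", {
  set.seed(66)
  for (i in 1:15) {
    n_met <- sample(100:3000, 1)
    recs <- data.frame(
      accession = sprintf("R%05d", seq_len(n_met)),
      name = sprintf("met %d", seq_len(n_met)),
      monoisotopic_mass = stats::runif(n_met, 60, 900)
    )
    db <- adduct_database_from_records(recs, "positive")
    # queries: some jittered DB entries, some uniform misses
    q <- c(
      sample(db$theoretical_mz, 30) * (1 + stats::rnorm(30, 0, 3e-6)),
      stats::runif(20, 60, 950)
    )
    m <- feature_matrix(seq_along(q), sort(q), matrix(1, length(q), 1), "s",
      polarity = "positive"
    )
    t <- sample(c(3, 6, 20), 1)
    ann <- annotate_matrix(m, db, t)
    expect_equal(ann$n_matches, oracle_match_count(m$mean_mz, db, t))
    # reported matches satisfy the ppm bound exactly
    audit <- attr(ann, "match_audit")
    expect_true(all(audit$ppm <= t))
    expect_equal(audit$ppm, oracle_ppm(audit$mean_mz, audit$theoretical_mz))
    # annotation never alters the matrix geometry
    expect_equal(ann$mean_mz, m$mean_mz)
    expect_equal(ann$s, m$s)
    expect_equal(nrow(ann), nrow(m))
  }
})

test_that("annotation rejects a polarity mismatch and works on re-read matrices", {
  db_neg <- build_adduct_database(fixture_xml(), "negative")
  m <- feature_matrix(1L, 181.070666, matrix(1, 1, 1), "s", polarity = "positive")
  expect_error(annotate_matrix(m, db_neg, 6), "polarit")
  # annotate a matrix re-read from its CSV (file-based entry path)
  path <- write_matrix(m, file.path(tempfile(), "x"))[1]
  back <- read_matrix_csv(path, "positive")
  ann <- annotate_matrix(back, build_adduct_database(fixture_xml(), "positive"), 6)
  expect_equal(ann$n_matches, 1L)
})
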