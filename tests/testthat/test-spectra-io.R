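test_that("peak list CSVs are read sorted, with header detection and duplicate merging", {
  p1 <- write_peaks_csv(tempfile(fileext = ".csv"), c("150.0,1000", "100.0,50"))
  s1 <- read_centroid_csv(p1, label = "a")
  expect_equal(s1$mz, c(100.0, 150.0))
  expect_equal(s1$intensity, c(50, 1000))

  p2 <- write_peaks_csv(tempfile(fileext = ".csv"), c("mz,intensity", "212.075,7"))
  s2 <- read_centroid_csv(p2)
  expect_equal(nrow(s2), 1L)
  expect_equal(s2$mz, 212.075)

  # duplicate-merge rule: intensities at one exact m/z sum
  p3 <- write_peaks_csv(tempfile(fileext = ".csv"), c("200.0,10", "200.0,5"))
  s3 <- read_centroid_csv(p3)
  expect_equal(s3$mz, 200.0)
  expect_equal(s3$intensity, 15)
})

test_that("malformed peak lists raise distinct labelled errors", {
  expect_error(read_centroid_csv(tempfile()), "not found")
  empty <- write_peaks_csv(tempfile(fileext = ".csv"), character(0))
  expect_error(read_centroid_csv(empty), "empty")
  header_only <- write_peaks_csv(tempfile(fileext = ".csv"), "mz,intensity")
  expect_error(read_centroid_csv(header_only), "no data rows")
  bad <- write_peaks_csv(tempfile(fileext = ".csv"), c("100.0,50", "abc,2"))
  expect_error(read_centroid_csv(bad), "non-numeric")
  neg <- write_peaks_csv(tempfile(fileext = ".csv"), "100.0,-5")
  expect_error(read_centroid_csv(neg), "negative intensity")
})

test_that("read_centroid_csv output m/z is strictly increasing on random files", {
  set.seed(11)
  for (i in 1:20) {
    mz <- round(stats::runif(50, 80, 1000), 4) # rounding forces some duplicates
    p <- tempfile(fileext = ".csv")
    utils::write.table(data.frame(mz, intensity = stats::rlnorm(50, 5, 1)),
      p,
      sep = ",", row.names = FALSE, col.names = FALSE
    )
    s <- read_centroid_csv(p)
    expect_true(all(diff(s$mz) > 0))
  }
})

test_that("manifest order equals batch order and shared blanks are accepted", {
  dir <- tempfile()
  dir.create(dir)
  for (f in c("s1", "s2", "s3")) {
    write_peaks_csv(file.path(dir, paste0(f, ".csv")), sprintf("%.1f,100", 100 + 1:3))
  }
  write_peaks_csv(file.path(dir, "bl.csv"), "500.0,10")
  # shuffled row order must be preserved exactly
  writeLines(c(
    "sample_file,blank_file,label",
    "s2.csv,bl.csv,beta", "s3.csv,bl.csv,gamma", "s1.csv,bl.csv,alpha"
  ), file.path(dir, "manifest.csv"))
  batch <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(batch_labels <- vapply(batch$pairs, function(p) attr(p$sample, "label"), ""),
    c("beta", "gamma", "alpha"),
    ignore_attr = TRUE
  )
  # N:1 blanks: the shared blank is identical across pairs
  expect_equal(batch$pairs[[1]]$blank$mz, batch$pairs[[3]]$blank$mz)
})

test_that("manifest errors name the offending row", {
  dir <- tempfile()
  dir.create(dir)
  write_peaks_csv(file.path(dir, "s1.csv"), "100.0,1")
  writeLines(c("sample_file,blank_file,label", "s1.csv,missing_blank.csv,a"),
    file.path(dir, "manifest.csv")
  )
  expect_error(read_manifest(file.path(dir, "manifest.csv")), "row 1.*missing_blank")
  writeLines("sample_file,blank_file,label", file.path(dir, "manifest.csv"))
  expect_error(read_manifest(file.path(dir, "manifest.csv")), "empty manifest")
})

test_that("matrix file suffixes follow the naming convention", {
  m <- feature_matrix(1:3, c(100, 200, 300),
    matrix(1:6, nrow = 3),
    c("a", "b"),
    polarity = "positive"
  )
  base <- file.path(tempfile(), "run")
  expect_match(write_matrix(m, base)[1], "_alignment_data\\.csv$")
  expect_match(write_matrix(m, base, sorted_by_adducts = TRUE)[1],
    "_alignment_data_sorted\\.csv$")
  ann <- annotate_matrix(m, adduct_database_from_records(
    data.frame(accession = "X1", name = "x", monoisotopic_mass = 150),
    "positive"
  ), 6)
  expect_match(write_matrix(ann, base)[1], "_HMDB_ID\\.csv$")
})

test_that("feature matrix CSV round-trip is value-identical with missing markers", {
  m <- feature_matrix(c(1L, 3L, 7L), c(100.123456, 250.5, 999.999),
    matrix(c(1.5, NA, 3, NA, 5, 6), nrow = 3),
    c("s1", "s2"),
    polarity = "negative"
  )
  base <- file.path(tempfile(), "rt")
  path <- write_matrix(m, base)[1]
  back <- read_matrix_csv(path, polarity = "negative")
  expect_equal(back$feature_id, m$feature_id)
  expect_equal(back$mean_mz, m$mean_mz)
  expect_equal(back$s1, m$s1)
  expect_equal(back$s2, m$s2)
  # and writing the re-read matrix reproduces the file byte for byte
  base2 <- file.path(tempfile(), "rt")
  path2 <- write_matrix(back, base2)[1]
  expect_identical(readLines(path), readLines(path2))
})
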