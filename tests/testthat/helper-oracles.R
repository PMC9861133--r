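# Brute-force reference implementations and fixture builders. These stay
# deliberately naive (all-pairs loops, linear scans) so they are an
# independent check on the package's windowed/greedy code paths.

oracle_ppm <- function(a, b) abs(a - b) / b * 1e6

# All-pairs blank subtraction: for every sample peak, scan every blank
# peak, keep candidates within t, subtract the argmin (tie: lower mz).
oracle_subtract <- function(sample_df, blank_df, t) {
  out_mz <- numeric(0)
  out_int <- numeric(0)
  for (i in seq_len(nrow(sample_df))) {
    s_mz <- sample_df$mz[i]
    s_int <- sample_df$intensity[i]
    d <- oracle_ppm(s_mz, blank_df$mz)
    cand <- which(d <= t)
    if (length(cand)) {
      best <- cand[order(d[cand], blank_df$mz[cand])[1L]]
      s_int <- max(0, s_int - blank_df$intensity[best])
    }
    if (s_int > 0) {
      out_mz <- c(out_mz, s_mz)
      out_int <- c(out_int, s_int)
    }
  }
  data.frame(mz = out_mz, intensity = out_int)
}

# Linear-scan annotation match counts against an adduct DB table.
oracle_match_count <- function(mzs, db_df, t) {
  vapply(mzs, function(m) sum(oracle_ppm(m, db_df$theoretical_mz) <= t), integer(1L))
}

random_spectrum <- function(n, label = "s", mz_range = c(80, 1000),
                            polarity = "positive") {
  centroid_spectrum(
    stats::runif(n, mz_range[1L], mz_range[2L]),
    stats::rlnorm(n, 6, 2),
    label = label, polarity = polarity
  )
}

make_spectrum <- function(mz, intensity, label = "s", polarity = "positive") {
  centroid_spectrum(mz, intensity, label = label, polarity = polarity)
}

write_peaks_csv <- function(path, lines) {
  writeLines(lines, path)
  path
}

fixture_xml <- function() {
  system.file("extdata", "synthetic_metabolites_hmdb_style.xml",
    package = "fiaprep", mustWork = TRUE
  )
}
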