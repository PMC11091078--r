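test_that("CSV, MGF and mzML inputs produce equivalent spectra", {
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("269.0,100", "254.1,40"), csv)
  s_csv <- read_spectrum(csv)
  expect_identical(nrow(s_csv$peaks), 2L)
  expect_equal(s_csv$peaks$mz, c(254.1, 269.0))  # sorted ascending

  mgf <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=demo", "PEPMASS=271.06", "153.0 10",
               "213.1 20", "269.1 100", "END IONS"), mgf)
  s_mgf <- read_spectrum(mgf)
  expect_equal(s_mgf$precursor_mz, 271.06)
  expect_identical(nrow(s_mgf$peaks), 3L)

  mzml <- withr::local_tempfile(fileext = ".mzML")
  make_mzml(mzml, c(153.0, 213.1, 269.1), c(10, 20, 100), precursor = 271.06)
  s_mzml <- read_spectrum(mzml)
  expect_identical(s_mzml$ms_level, 2L)
  expect_equal(s_mzml$peaks$mz, c(153.0, 213.1, 269.1))
  expect_equal(s_mzml$precursor_mz, 271.06)
})

test_that("malformed or empty inputs are rejected with a location", {
  bad <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "269.0 xx", "END IONS"), bad)
  expect_error(read_spectrum(bad), "malformed")
  empty <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=100", "END IONS"), empty)
  expect_error(read_spectrum(empty), "empty")
  expect_error(ms_spectrum(numeric(0), numeric(0)))
  expect_error(ms_spectrum(c(100, NaN), c(1, 1)), "finite")
})

test_that("top-peak selection caps at 100, is idempotent and order-invariant", {
  s3 <- ms_spectrum(c(100, 200, 300), c(1, 2, 3))
  expect_identical(nrow(select_top_peaks(s3, 100)$peaks), 3L)

  set.seed(20)
  mz <- seq(100, 100 + 149 * 0.7, by = 0.7)
  it <- runif(150, 1, 1000)
  s150 <- ms_spectrum(mz, it)
  kept <- select_top_peaks(s150, 150)
  expect_identical(nrow(kept$peaks), 100L)
  # re-selection changes nothing
  expect_equal(select_top_peaks(kept, 150)$peaks, kept$peaks)
  # permuting the input peak order changes nothing
  perm <- sample(150)
  s_perm <- ms_spectrum(mz[perm], it[perm])
  expect_equal(select_top_peaks(s_perm, 150)$peaks, kept$peaks)
})

test_that("intensity ties break toward the lower m/z", {
  s <- ms_spectrum(c(100, 150, 200), c(5, 5, 5))
  kept <- select_top_peaks(s, 2)
  expect_equal(kept$peaks$mz, c(100, 150))
})

test_that("peak-cluster merging computes the weighted centroid", {
  s <- ms_spectrum(c(268.9, 269.0, 269.1), c(10, 10, 10))
  m <- merge_peak_cluster(s, 269.0, window = 1)
  expect_equal(m$mz, 269.0)
  expect_equal(m$intensity, 30)
  # asymmetric cluster equals the direct weighted-mean oracle
  s2 <- ms_spectrum(c(268.9, 269.0, 269.1), c(5, 20, 2))
  m2 <- merge_peak_cluster(s2, 269.0, window = 1)
  expect_equal(m2$mz, sum(c(268.9, 269.0, 269.1) * c(5, 20, 2)) / 27)
  # isolated peak, window 0
  m0 <- merge_peak_cluster(s2, 269.1, window = 0)
  expect_equal(m0$mz, 269.1)
  expect_error(merge_peak_cluster(s2, 300), "not found")
})

test_that("scan averaging aligns and averages repeat measurements", {
  a <- ms_spectrum(c(153.0, 269.1), c(10, 100), precursor_mz = 271.1)
  b <- ms_spectrum(c(153.1, 269.0), c(14, 80))
  avg <- average_spectra(list(a, b), tol = 0.3)
  expect_identical(nrow(avg$peaks), 2L)
  expect_equal(avg$peaks$mz[1], 153.05)
  expect_equal(avg$peaks$intensity[1], 12)
  expect_equal(avg$precursor_mz, 271.1)
})

test_that("m/z encoding truncates (never rounds) at two decimals", {
  s <- ms_spectrum(c(153.999, 269.0, 271.068), c(1, 2, 3))
  expect_identical(as.integer(encode_spectrum(s)), c(15399L, 26900L, 27106L))
  # truncation differs from rounding on x.xx9 values
  expect_false(15400L %in% encode_spectrum(s))
  # token/100 is within 0.01 Da of the source m/z (property over random peaks)
  set.seed(33)
  mz <- runif(100, 50, 500)
  tok <- encode_spectrum(ms_spectrum(mz, rep(1, 100)))
  expect_true(all(sort(mz) - as.integer(tok) / 100 < 0.01))
  expect_true(all(sort(mz) - as.integer(tok) / 100 >= 0))
  expect_lte(length(tok), 100L)
})
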