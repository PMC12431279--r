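test_that("signal_record validates its invariants", {
  r <- signal_record(c(1, 2, 3), fs = 250, kind = "ECG")
  expect_s3_class(r, "signal_record")
  expect_equal(length(r), 3L)
  expect_equal(record_times(r), c(0, 1, 2) / 250)
  expect_error(signal_record(numeric(0), 250), "at least one")
  expect_error(signal_record(c(1, NA), 250), "non-finite")
  expect_error(signal_record(1:3, -1), "positive")
})

test_that("CSV record round-trip preserves samples and never resamples", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("value", "0.1", "0.2", "0.3", "0.4", "0.5"), tmp)
  r <- read_record(tmp, "csv", fs = 250)
  expect_equal(length(r), 5L)
  expect_equal(r$fs, 250)
  expect_equal(r$samples, c(0.1, 0.2, 0.3, 0.4, 0.5))

  cfg <- synth_config(duration = 10, seed = 3)
  rec <- synthesize_ecg(synthesize_beats(cfg), cfg)
  out <- withr::local_tempfile(fileext = ".csv")
  write_record(rec, out)
  back <- read_record(out, "csv", fs = rec$fs)
  expect_equal(length(back), length(rec))
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)

  expect_error(read_record(tmp, "csv"), "fs")
  expect_error(read_record(tmp, "csv", channel = "nope", fs = 250), "channel")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("value", "1.0", "oops"), bad)
  expect_error(read_record(bad, "csv", fs = 250), "non-numeric")
})

test_that("beat-annotation CSV reading enforces monotonicity", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines("10,260,510", tmp)
  a <- read_annotations(tmp, "csv")
  expect_equal(a$peak_indices, c(10L, 260L, 510L))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("10,5", bad)
  expect_error(read_annotations(bad, "csv"), "increasing")

  hdr <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample", "100", "350"), hdr)
  expect_equal(read_annotations(hdr, "csv")$peak_indices, c(100L, 350L))
})

test_that("heart-rate CSV round-trip preserves values to 9+ significant digits", {
  hr <- hr_series(seq(0, 2, by = 0.5), c(1.123456789012, 1.2, 0.987654321987,
                                         1.05, 1.1), "rpeak")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_hr(hr, tmp)
  lines <- readLines(tmp)
  expect_equal(lines[1], "time_s,hr_hz,provenance")
  expect_equal(length(lines), 6L)
  back <- read_hr(tmp)
  expect_equal(back$times, hr$times, tolerance = 1e-9)
  expect_equal(back$values, hr$values, tolerance = 1e-9)
  expect_equal(back$provenance, "rpeak")
  expect_error(write_hr(list(), tmp))
})

test_that("WFDB format-212 records read back with header gain/baseline applied", {
  dir <- withr::local_tempdir()
  # two channels with known ADC values incl. negative ones
  adc1 <- c(0L, 100L, -100L, 1023L, -1024L, 512L)
  adc2 <- c(5L, -5L, 200L, -200L, 7L, -2047L)
  hea <- write_wfdb_fixture(dir, "rec01", adc1, adc2, fs = 360,
                            gain = 200, baseline = 10)
  r1 <- read_record(hea, "wfdb", channel = 1)
  expect_equal(r1$fs, 360)
  expect_equal(r1$samples, (adc1 - 10) / 200)
  r2 <- read_record(file.path(dir, "rec01"), "wfdb", channel = "ch2")
  expect_equal(r2$samples, (adc2 - 10) / 200)
  expect_error(read_record(hea, "wfdb", channel = 3), "channel")
})

test_that("MIT annotation decoding keeps beat classes and drops the rest", {
  tmp <- withr::local_tempfile(fileext = ".atr")
  # samples (0-based) and codes: NORMAL=1, PVC=5, rhythm-change=28 (drop),
  # noise=14 (drop), APC=8
  write_atr_fixture(tmp, c(100L, 350L, 500L, 620L, 900L),
                    codes = c(1L, 5L, 28L, 14L, 8L))
  a <- read_annotations(tmp, "wfdb")
  expect_equal(a$peak_indices, c(100L, 350L, 900L) + 1L)
  expect_equal(a$source, "expert")
})

test_that("EDF records scale digital values by the header calibration", {
  tmp <- withr::local_tempfile(fileext = ".edf")
  dig <- as.integer(round(seq(-2048, 2047, length.out = 100)))
  write_edf_fixture(tmp, list(dig, rev(dig)), fs = 100, rec_dur = 1,
                    pmin = c(-5, -1), pmax = c(5, 1),
                    dmin = c(-2048, -2048), dmax = c(2047, 2047),
                    labels = c("ECG", "PPG"))
  r <- read_record(tmp, "edf", channel = "ECG")
  expect_equal(r$fs, 100)
  expect_equal(length(r), 100L)
  scale <- 10 / (2047 + 2048)
  expect_equal(r$samples, -5 + (dig + 2048) * scale, tolerance = 1e-9)
  r2 <- read_record(tmp, "edf", channel = 2)
  expect_equal(r2$samples, -1 + (rev(dig) + 2048) * 2 / 4095, tolerance = 1e-9)
})
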