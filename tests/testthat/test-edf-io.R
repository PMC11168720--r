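# EDF round trip, channel mapping, annotation parsing

test_that("EDF write/read round-trips signals, labels and rates", {
  set.seed(101)
  sig <- matrix(rnorm(30 * 512 * 4, 0, 50), 30)
  labs <- c(paste("EEG", montage_labels()), "ECG")
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(f, sig, 512, labs)
  e <- read_edf(f)
  expect_identical(e$labels, labs)
  expect_equal(unique(e$fs), 512)
  expect_equal(dim(e$signals), dim(sig))
  # 16-bit quantisation of a ~414 uV range: worst case half an LSB each way
  lsb <- diff(range(sig)) / 65535
  expect_lt(max(abs(e$signals - sig)), 1.1 * lsb)
})

test_that("read_recording maps the 29-channel montage and flags gaps", {
  set.seed(102)
  ref <- montage_labels()
  sig <- matrix(rnorm(30 * 512 * 2), 30)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(f, sig, 512, c(paste("EEG", ref), "ECG EKG"))
  rr <- read_recording(f)
  expect_s3_class(rr$recording, "physio_recording")
  expect_identical(rr$recording$channel_labels, ref)
  expect_equal(nrow(rr$recording$montage_xy), 29)

  # reduced montage: the 10 derivations absent for one study subject
  absent <- c("Fc1", "Fc5", "Cp1", "Cp5", "F9", "Fc2", "Fc6", "Cp2",
              "Cp6", "F10")
  keep <- c(which(!ref %in% absent), 30L)
  f2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(f2, sig[keep, ], 512, c(paste("EEG", ref), "ECG")[keep])
  expect_warning(r2 <- read_recording(f2), "absent")
  expect_equal(nrow(r2$recording$eeg), 19)
  expect_false(any(absent %in% r2$recording$channel_labels))
})

test_that("a recording without ECG or EEG is rejected", {
  sig <- matrix(rnorm(512 * 2), 1)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(f, sig, 512, "ECG")
  expect_error(read_recording(f), "EEG")
  f2 <- withr::local_tempfile(fileext = ".edf")
  write_edf(f2, sig, 512, "EEG Cz")
  expect_error(read_recording(f2), "ECG")
})

test_that("annotations parse seconds and clock-time dialects", {
  f <- withr::local_tempfile()
  writeLines(c("# onset offset", "900 960", "1500.5, 1570.25"), f)
  a <- read_annotations(f)
  expect_equal(a$onset_s, c(900, 1500.5))
  expect_equal(a$offset_s, c(960, 1570.25))

  f2 <- withr::local_tempfile()
  writeLines("00:20:00 00:21:30", f2)
  a2 <- read_annotations(f2, start_time = "00.05.00")
  expect_equal(a2$onset_s, 900)
  expect_equal(a2$offset_s, 990)
  # clock time past midnight relative to an evening start
  f3 <- withr::local_tempfile()
  writeLines("00:10:00 00:12:00", f3)
  a3 <- read_annotations(f3, start_time = "23.50.00")
  expect_equal(a3$onset_s, 1200)
  expect_error(read_annotations(
    { f4 <- withr::local_tempfile(); writeLines("5 4", f4); f4 }),
    "offset")
})

test_that("simulated sessions survive the EDF round trip", {
  sc <- small_scenario()
  sim <- simulate_session(sc, seed = 3)
  d <- withr::local_tempdir()
  paths <- write_session(sim, d)
  expect_warning(got <- read_recording(paths["edf"], paths["annotations"]),
                 "absent")   # 12-channel montage subset
  expect_equal(nrow(got$recording$eeg), 12)
  expect_equal(got$annotations$onset_s, sim$annotations$onset_s)
  # quantised signals stay close to the originals
  i <- seq_len(2000)
  expect_gt(stats::cor(got$recording$ecg[i], sim$recording$ecg[i]), 0.999)
})
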