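# R-peak detection and RR-series conditioning

test_that("detector recovers a regular pulse train to within one sample", {
  fs <- 512
  bt <- seq(0.5, 59.5, by = 0.8)
  ecg <- fixture_ecg(bt, fs, 60)
  det <- detect_rpeaks(ecg, fs)
  expect_equal(length(det), length(bt))
  err <- vapply(det, function(d) min(abs(d - bt)), numeric(1)) * fs
  expect_lte(max(err), 1)
})

test_that("a halved-amplitude pulse is still detected", {
  fs <- 512
  bt <- seq(0.5, 59.5, by = 0.8)
  ecg <- fixture_ecg(bt, fs, 60)
  i0 <- round(bt[20] * fs) + 1L
  sel <- (i0 - 30):(i0 + 30)
  ecg[sel] <- ecg[sel] / 2
  expect_equal(length(detect_rpeaks(ecg, fs)), length(bt))
})

test_that("detection holds at 20 dB SNR and varying rate", {
  set.seed(201)
  fs <- 512
  # slowly modulated rhythm around 75 bpm
  bt <- ipfm_generate(function(t) 0.04 * sin(2 * pi * 0.1 * t), 75, 120)
  ecg <- fixture_ecg(bt, fs, 120)
  ecg <- ecg + rnorm(length(ecg), 0, sqrt(mean(ecg^2) / 100))
  det <- detect_rpeaks(ecg, fs)
  hits <- vapply(bt, function(b) min(abs(det - b)) <= 1 / fs + 1e-9, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("flat or empty signals yield an empty result with a warning", {
  expect_warning(r <- detect_rpeaks(rep(0, 512 * 15), 512), "QRS")
  expect_length(r, 0)
  expect_error(detect_rpeaks(rnorm(100), 512), "10 s")
})

test_that("median-rule artifact correction replaces outliers only", {
  bt <- cumsum(c(0, rep(0.8, 50)))
  rr <- rr_series(bt)
  rr$rr_s[25] <- 2.4
  out <- correct_rr_artifacts(rr)
  expect_equal(out$n_corrected, 1L)
  expect_equal(out$rr_s[25], 0.8, tolerance = 1e-6)
  expect_equal(out$rr_s[-25], rr$rr_s[-25])     # untouched elsewhere
  expect_length(out$rr_s, length(rr$rr_s))      # sample count preserved
  expect_false(out$quality_warning)

  clean <- correct_rr_artifacts(rr_series(bt))
  expect_equal(clean$rr_s, diff(bt))
  expect_equal(clean$n_corrected, 0L)
})

test_that("bigeminy-like alternation triggers the quality warning", {
  rr <- rr_series(cumsum(c(0, rep(c(0.4, 1.6), 25))))
  expect_warning(out <- correct_rr_artifacts(rr), "quality")
  expect_true(out$quality_warning)
  expect_length(out$rr_s, 50)
})

test_that("cubic 4 Hz resampling reproduces constants and ramps", {
  rr <- interpolate_rr(rr_series(cumsum(c(0, rep(1, 30)))))
  expect_equal(unique(round(diff(rr$t4hz), 10)), 0.25)
  expect_equal(rr$rr4hz, rep(1, length(rr$rr4hz)), tolerance = 1e-9)

  bt <- cumsum(c(0, seq(0.8, 1.2, length.out = 40)))
  rrr <- interpolate_rr(rr_series(bt))
  truth <- stats::approx(bt[-1], diff(bt), xout = rrr$t4hz)$y
  expect_lt(max(abs(rrr$rr4hz - truth)), 1e-3)

  expect_error(interpolate_rr(rr_series(c(0, 1, 2))), "4 beats")
})
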