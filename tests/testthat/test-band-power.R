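# time-resolved band power: Hilbert-envelope (EEG) and SPWVD (HRV)

test_that("band definitions carry the study's band edges and tone centres", {
  th <- band_definition("theta")
  expect_equal(c(th$lo_hz, th$hi_hz), c(4, 8))
  expect_equal(th$omega_center, 2 * pi * 6)
  expect_equal(band_definition("LF")$hi_hz, 0.15)
  expect_equal(band_definition("HF")$lo_hz, 0.15)
  expect_error(band_definition("gamma"), "unknown")
})

test_that("EEG envelope recovers tone power A^2/2 with small cross-band leakage", {
  fs <- 512
  tt <- seq(0, 60, by = 1 / fs)[-1]
  for (case in list(list(f = 2.5, band = "delta"), list(f = 6, band = "theta"),
                    list(f = 10, band = "alpha"), list(f = 20, band = "beta"))) {
    bp <- eeg_band_power(10 * sin(2 * pi * case$f * tt), fs, case$band)
    expect_equal(median(bp$power), 50, tolerance = 0.1)
    expect_equal(bp$amplitude, sqrt(2 * bp$power))
  }
  s6 <- 10 * sin(2 * pi * 6 * tt)
  leak <- median(eeg_band_power(s6, fs, "alpha")$power) /
    median(eeg_band_power(s6, fs, "theta")$power)
  expect_lt(leak, 0.05)
  # white noise: power positive everywhere
  set.seed(31)
  bpn <- eeg_band_power(rnorm(length(tt)), fs, "alpha")
  expect_true(all(bpn$power > 0))
})

test_that("SPWVD recovers HRV tone power in the right band", {
  tt <- seq(0, 300, by = 0.25)
  x <- 0.9 + 0.02 * sin(2 * pi * 0.25 * tt)     # HF tone
  hf <- hrv_band_power(x, "HF")
  lf <- hrv_band_power(x, "LF")
  expect_equal(median(hf$power), 2e-4, tolerance = 0.2)
  expect_lt(median(lf$power), 0.1 * median(hf$power))

  y <- 0.9 + 0.02 * sin(2 * pi * 0.1 * tt)      # LF tone, symmetric check
  expect_equal(median(hrv_band_power(y, "LF")$power), 2e-4, tolerance = 0.2)
  expect_lt(median(hrv_band_power(y, "HF")$power),
            0.1 * median(hrv_band_power(y, "LF")$power))

  # constant series: both bands ~ 0
  z <- rep(0.9, length(tt))
  expect_lt(median(hrv_band_power(z, "HF")$power), 1e-12)
  expect_error(hrv_band_power(x, "delta"), "HRV band")
  expect_error(hrv_band_power(x[1:100], "LF"), "shorter")
})

test_that("the Welch cross-check agrees with the SPWVD on stationary tones", {
  tt <- seq(0, 300, by = 0.25)
  x <- 0.9 + 0.02 * sin(2 * pi * 0.25 * tt)
  a <- median(hrv_band_power(x, "HF", method = "spwvd")$power)
  b <- median(hrv_band_power(x, "HF", method = "welch")$power)
  expect_equal(a, b, tolerance = 0.15)
})

test_that("band power estimation is shift-stationary and grid-aligned", {
  fs <- 128
  tt <- seq(0, 80, by = 1 / fs)[-1]
  x <- (2 + sin(2 * pi * 0.05 * tt)) * sin(2 * pi * 6 * tt)
  p0 <- eeg_band_power(x, fs, "theta")
  # shifting the signal by 10 s shifts the power series by 10 s
  sh <- 10
  x2 <- (2 + sin(2 * pi * 0.05 * (tt + sh))) * sin(2 * pi * 6 * (tt + sh))
  p2 <- eeg_band_power(x2, fs, "theta")
  i <- 20:50
  expect_equal(p2$power[i], p0$power[i + sh], tolerance = 0.02)
  # grids are uniform with the requested step
  expect_equal(unique(round(diff(p0$t_s), 9)), 1)
})
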