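# forward simulator: determinism, decoupled limits, parameter recovery

test_that("identical (scenario, seed) reproduces the session bit-for-bit", {
  sc <- small_scenario()
  s1 <- simulate_session(sc, seed = 7)
  s2 <- simulate_session(sc, seed = 7)
  expect_identical(s1$recording$eeg, s2$recording$eeg)
  expect_identical(s1$recording$ecg, s2$recording$ecg)
  expect_identical(s1$truth$beats, s2$truth$beats)
  s3 <- simulate_session(sc, seed = 8)
  expect_false(identical(s1$recording$ecg, s3$recording$ecg))
})

test_that("the decoupled noiseless limit gives constant envelopes and exact RR", {
  sc <- sim_scenario(eeg_bands = "delta", hrv_bands = "LF", n_channels = 3,
                     window_len_s = 120, onset_s = 180, offset_s = 210,
                     htb_base = matrix(0, 1, 1,
                                       dimnames = list("delta", "LF")),
                     bth_base = 0, c_lf0 = 0, c_hf0 = 0,
                     eeg_noise_uV = 0, a_sd = 0, c_sd = 0, rr_jitter_s = 0,
                     event_jitter_sd = 0, hr_ref_bpm = 60)
  sim <- simulate_session(sc, seed = 1)
  expect_equal(diff(sim$truth$beats), rep(1, length(sim$truth$beats) - 1),
               tolerance = 1e-6)
  # band amplitude decays from a0 at rate eta and stays flat at the floor
  a <- sim$truth$a[, 1, 1]
  expect_equal(stats::sd(a[150:300]), 0)
})

test_that("series-level parameter recovery at 20 dB holds across seeds", {
  set.seed(71)
  errs <- replicate(60, {
    n <- 300
    pb <- 100 * (1 + runif(n))
    sig_c <- stats::sd(3e-4 * pb)
    fw <- sdg_forward(n, sdg_bth = 3e-4, sdg_htb = 1500, eta = 0.8,
                      c0 = 0.03, p_brain = pb, noise_c = sig_c / 10)
    f <- estimate_bth(fw$c_i, pb, window_s = 60)
    abs(median(coef(f)[, "sdg"]) - 3e-4) / 3e-4
  })
  expect_lte(median(errs), 0.10)
})

test_that("cohort simulation enforces the minimum event count and null mode", {
  expect_error(simulate_cohort(3), "at least 6")
  sc <- small_scenario()
  co <- simulate_cohort(6, sc, seed = 2, null_mode = TRUE)
  expect_length(co, 6)
  expect_true(all(vapply(co, function(s)
    all(s$truth$post_fac == 1), logical(1))))
})

test_that("planted effect multiplies only the requested channels and pair", {
  sc <- sim_scenario(eeg_bands = c("delta", "theta"), hrv_bands = "LF",
                     n_channels = 29, window_len_s = 120,
                     onset_s = 180, offset_s = 210)
  sim <- simulate_session(sc, seed = 4)
  pf <- sim$truth$post_fac
  planted <- dimnames(pf)[[1]] %in% sc$effect$channels
  expect_equal(unname(pf[planted, "delta", "LF"]),
               rep(1 / 3, sum(planted)))
  expect_true(all(pf[!planted, , ] == 1))
  expect_true(all(pf[, "theta", ] == 1))
})

test_that("an end-to-end planted brain-to-heart drop shows in the medians", {
  # theta -> HF coupling drops to one tenth after the seizure; the
  # modulation amplitude regression should see a lower coefficient
  sc <- sim_scenario(eeg_bands = c("delta", "theta"), hrv_bands = "HF",
                     n_channels = 3, window_len_s = 240,
                     onset_s = 300, offset_s = 330,
                     bth_base = 1.5e-5, a_sd = 4, c_sd = 0.002,
                     effect = list(direction = "bth", hrv_band = "HF",
                                   eeg_band = "theta", channels = 1:3,
                                   post_factor = 0.1))
  pre <- post <- c()
  for (sd in 1:3) {
    sim <- simulate_session(sc, seed = sd)
    win <- extract_windows(sim$recording, sim$annotations[1, ],
                           window_len_s = 240, event_id = "e")
    co <- compute_bhi_event(sim$recording, win, eeg_bands = "theta",
                            hrv_bands = "HF", directions = "bth")
    s <- event_phase_summary(co, win)$phase_median
    pre <- c(pre, s$median_coeff[s$phase == "preictal"])
    post <- c(post, s$median_coeff[s$phase == "postictal"])
  }
  expect_lt(median(post), median(pre))
})
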