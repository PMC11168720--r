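# fixture builders shared across test files (built in code, never stored)

# ECG pulse train: sharp positive QRS-like template at given beat times
fixture_ecg <- function(beat_times_s, fs, duration_s, amp = 1, sigma_s = 0.012,
                        noise_sd = 0) {
  n <- round(duration_s * fs)
  ecg <- numeric(n)
  half <- round(5 * sigma_s * fs)
  w <- -half:half
  tpl <- amp * (1 - (w / fs / sigma_s)^2) * exp(-(w / fs)^2 / (2 * sigma_s^2))
  for (bt in beat_times_s) {
    i <- round(bt * fs) + 1L
    sel <- (i - half):(i + half)
    keep <- sel >= 1 & sel <= n
    ecg[sel[keep]] <- ecg[sel[keep]] + tpl[keep]
  }
  if (noise_sd > 0) ecg <- ecg + stats::rnorm(n, 0, noise_sd)
  ecg
}

# brute-force two-sided signed-rank p by full 2^n enumeration (oracle)
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 14)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ws <- vapply(0:(2^n - 1), function(m) {
    s <- as.integer(intToBits(m))[1:n]
    sum(r[s == 1L])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}

# small scenario used by pipeline-level tests (cheap but full-featured)
small_scenario <- function(...) {
  sim_scenario(eeg_bands = "delta", hrv_bands = "LF", n_channels = 12L,
               window_len_s = 120, onset_s = 180, offset_s = 210, ...)
}
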