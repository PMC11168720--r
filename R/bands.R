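#' Frequency band definitions
#'
#' The analysis works with four EEG bands (delta 1-4 Hz, theta 4-8 Hz,
#' alpha 8-12 Hz, beta 12-30 Hz) and two heart-rate-variability bands
#' (LF 0.04-0.15 Hz, sympathovagal; HF 0.15-0.4 Hz, vagal/respiratory).
#' Each band carries a central angular frequency `omega_center`
#' (\eqn{2\pi (lo + hi)/2}) used as the carrier of the sinusoidal forward
#' model.
#'
#' @param name one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"LF"`, `"HF"`.
#' @return a list of class `band_definition` with fields `name`, `lo_hz`,
#'   `hi_hz`, `omega_center`, `kind` (`"eeg"` or `"hrv"`).
#' @examples
#' band_definition("theta")$omega_center / (2 * pi)  # 6 Hz
#' @export
band_definition <- function(name) {
  tab <- band_table()
  i <- match(name, tab$name)
  if (is.na(i)) stopf("unknown band '%s'", name)
  structure(list(name = tab$name[i], lo_hz = tab$lo[i], hi_hz = tab$hi[i],
                 omega_center = 2 * pi * (tab$lo[i] + tab$hi[i]) / 2,
                 kind = tab$kind[i]),
            class = "band_definition")
}

band_table <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "LF", "HF"),
             lo = c(1, 4, 8, 12, 0.04, 0.15),
             hi = c(4, 8, 12, 30, 0.15, 0.40),
             kind = c(rep("eeg", 4), rep("hrv", 2)),
             stringsAsFactors = FALSE)
}

#' @rdname band_definition
#' @export
eeg_bands <- function() c("delta", "theta", "alpha", "beta")

#' @rdname band_definition
#' @export
hrv_bands <- function() c("LF", "HF")

new_band_power_series <- function(band, t_s, power) {
  power <- pmax(power, 0)
  structure(list(band = band, t_s = t_s, power = power,
                 amplitude = sqrt(2 * power)),
            class = "band_power_series")
}

#' @export
print.band_power_series <- function(x, ...) {
  cat(sprintf("<band_power_series> %s (%.3g-%.3g Hz), %d points, step %.3g s\n",
              x$band$name, x$band$lo_hz, x$band$hi_hz, length(x$t_s),
              if (length(x$t_s) > 1) x$t_s[2] - x$t_s[1] else NA_real_))
  cat(sprintf("  median power %.4g, median amplitude %.4g\n",
              stats::median(x$power), stats::median(x$amplitude)))
  invisible(x)
}

#' Time-resolved EEG band power by Hilbert envelope
#'
#' Band-pass filters one EEG channel (zero-phase windowed-sinc FIR), takes the
#' squared analytic envelope halved (so a pure in-band sinusoid of amplitude
#' A yields power A^2/2), smooths with a moving average of the grid step, and
#' samples on a uniform coarse grid. The returned amplitude, sqrt(2 power),
#' equals the sinusoidal amplitude for a pure tone, matching the amplitude
#' convention of the coupling model.
#'
#' @param x numeric vector, one channel in microvolts.
#' @param fs sampling rate in Hz.
#' @param band an EEG `band_definition` (or band name).
#' @param grid_step_s coarse grid step in seconds (default 1).
#' @param t0_s time of the first sample (default 0), so grids from windows cut
#'   out of a longer record stay aligned.
#' @return a `band_power_series` (power in microvolt^2).
#' @export
eeg_band_power <- function(x, fs, band, grid_step_s = 1, t0_s = 0) {
  if (is.character(band)) band <- band_definition(band)
  if (band$kind != "eeg") stopf("eeg_band_power needs an EEG band, got '%s'", band$name)
  if (fs <= 2 * band$hi_hz) stopf("sampling rate %g Hz too low for band %s", fs, band$name)
  if (length(x) < 10 / band$lo_hz * fs)
    stopf("signal shorter than 10 cycles of the band lower edge")
  be <- band_envelope(x, fs, band$lo_hz, band$hi_hz)
  env2 <- be$env^2 / 2
  step <- max(1L, round(grid_step_s * be$fs_env))
  env2 <- moving_average(env2, step)
  idx <- seq(1L, length(env2), by = step)
  new_band_power_series(band, t0_s + (idx - 1L) / be$fs_env, env2[idx])
}

#' Time-resolved HRV band power by smoothed pseudo-Wigner-Ville distribution
#'
#' Computes a time-frequency power distribution of the (mean-removed) 4 Hz
#' resampled RR series with independent time and frequency smoothing, then
#' integrates it over the requested band per grid point. Normalised so a pure
#' tone of amplitude A integrates to power A^2/2 in its band. A Welch
#' sliding-window estimator is available as an independent cross-check.
#'
#' @param rr4hz numeric vector, RR series resampled at `fs_rr` Hz (seconds).
#' @param band an HRV `band_definition` (or `"LF"`/`"HF"`).
#' @param grid_step_s coarse grid step in seconds (default 1).
#' @param fs_rr sampling rate of `rr4hz` (default 4).
#' @param t0_s time of the first sample (default 0).
#' @param method `"spwvd"` (default) or `"welch"`.
#' @param time_smooth_s length of the Hamming time-smoothing window (default 5 s).
#' @param freq_smooth_hz approximate frequency smoothing bandwidth (default
#'   0.015 Hz), realised by the lag-window length.
#' @return a `band_power_series` (power in s^2).
#' @export
hrv_band_power <- function(rr4hz, band, grid_step_s = 1, fs_rr = 4, t0_s = 0,
                           method = c("spwvd", "welch"),
                           time_smooth_s = 5, freq_smooth_hz = 0.015) {
  if (is.character(band)) band <- band_definition(band)
  if (band$kind != "hrv") stopf("hrv_band_power needs an HRV band, got '%s'", band$name)
  n <- length(rr4hz)
  if (n < 2 / band$lo_hz * fs_rr)
    stopf("RR series shorter than 2 cycles of the band lower edge")
  method <- match.arg(method)
  x <- rr4hz - mean(rr4hz)
  step <- max(1L, round(grid_step_s * fs_rr))
  idx <- seq(1L, n, by = step)
  p <- if (method == "spwvd") {
    spwvd_band_power(x, fs_rr, band, idx, time_smooth_s, freq_smooth_hz)
  } else {
    welch_band_power(x, fs_rr, band, idx)
  }
  new_band_power_series(band, t0_s + (idx - 1L) / fs_rr, p)
}

# Smoothed pseudo-Wigner-Ville band power at selected sample indices.
# Works on the analytic signal; W[t,k] = FFT_m( h[m] * G(t,m) ) where
# G(t,m) = time-smoothed z[t+m] z*[t-m]. Band power = sum_k Re W / (2 Nf),
# so a real tone of amplitude A integrates to A^2/2 over all frequencies.
spwvd_band_power <- function(x, fs, band, idx, time_smooth_s, freq_smooth_hz) {
  n <- length(x)
  z <- analytic_signal(x)
  # lag (frequency-smoothing) window: Hamming, ~1.3*fs/L bandwidth
  Lh <- 2L * (round(1.3 * fs / freq_smooth_hz) %/% 2L) + 1L
  Lh <- min(Lh, 2L * ((n - 1L) %/% 2L) + 1L)
  M <- (Lh - 1L) %/% 2L
  h <- hamming_window(Lh)
  h <- h / h[M + 1L]                     # h[0] = 1 keeps marginals normalised
  Lg <- max(1L, 2L * (round(time_smooth_s * fs) %/% 2L) + 1L)
  g <- hamming_window(Lg); g <- g / sum(g)
  nf <- stats::nextn(max(2L * M + 1L, 256L), 2)
  nt <- length(idx)
  A <- matrix(0 + 0i, nrow = nf, ncol = nt)
  zp <- c(rep(0 + 0i, M), z, rep(0 + 0i, M))   # zero-pad edges
  # time smoothing evaluated only at the grid points: windowed weighted sums
  halfg <- (length(g) - 1L) %/% 2L
  offs <- -halfg:halfg
  J <- outer(idx, offs, "+")              # nt x Lg sample indices (1..n)
  Jok <- J >= 1L & J <= n
  J[!Jok] <- 1L
  wden <- as.numeric(Jok %*% g)           # renormalisation at window edges
  smooth_at <- function(pm) {
    vals <- matrix(pm[J], nrow = nt)
    vals[!Jok] <- 0
    (vals %*% g) / wden
  }
  for (m in 0:M) {
    # lag product for all t: z[t+m] z*[t-m], t = 1..n
    pm <- zp[(1L + M + m):(n + M + m)] * Conj(zp[(1L + M - m):(n + M - m)])
    v <- h[M + 1L + m] * smooth_at(pm)
    A[m + 1L, ] <- A[m + 1L, ] + v
    if (m > 0L) A[nf - m + 1L, ] <- A[nf - m + 1L, ] + Conj(v)
  }
  W <- Re(stats::mvfft(A))               # nf x nt, frequencies k*fs/(2*nf)
  f <- (0:(nf - 1L)) * fs / (2 * nf)
  sel <- f >= band$lo_hz & f < band$hi_hz
  pmax(colSums(W[sel, , drop = FALSE]) / (2 * nf), 0)
}

hamming_window <- function(n) {
  if (n == 1L) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1L)) / (n - 1L))
}

# Welch fallback: per grid point, Hann periodogram of a centred segment
welch_band_power <- function(x, fs, band, idx, seg_s = 120) {
  n <- length(x)
  L <- min(n, round(seg_s * fs))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1L)) / (L - 1L))
  U <- sum(w^2) / L
  vapply(idx, function(i) {
    lo <- max(1L, min(i - L %/% 2L, n - L + 1L))
    seg <- x[lo:(lo + L - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg))^2 / (L^2 * U)   # two-sided, per-bin
    f <- (0:(L - 1L)) * fs / L
    sel <- f >= band$lo_hz & f < band$hi_hz
    2 * sum(P[sel])                            # fold negative frequencies
  }, numeric(1))
}
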