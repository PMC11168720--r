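# EEG conditioning and analysis-window extraction

# windowed-sinc (Hamming) band-pass kernel; order ~ 3*fs/lo cycles of the
# lower edge, forced even so the kernel has integer group delay
fir_bandpass_kernel <- function(fs, lo_hz, hi_hz, order = NULL) {
  # ~3 cycles of the lower edge, rounded up to a multiple of 32 so the
  # group delay stays an integer multiple of any envelope decimation
  if (is.null(order)) order <- 32L * ceiling(3 * fs / lo_hz / 32)
  order <- as.integer(order + order %% 2L)
  as.numeric(signal::fir1(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass"))
}

# zero-phase FIR band-pass: convolve with b then with rev(b) == convolve once
# with the autocorrelation of b (exactly filtfilt's magnitude-squared
# response, without its edge reflection)
fir_bandpass_filter <- function(x, fs, lo_hz, hi_hz, order = NULL) {
  b <- fir_bandpass_kernel(fs, lo_hz, hi_hz, order)
  h <- stats::convolve(b, rev(b), type = "open")  # symmetric, odd length
  fft_conv_centered(x, h)
}

# zero-phase band-pass + instantaneous envelope in one frequency-domain
# pass: the Hilbert mask is applied on the same padded grid as the kernel
# product (wraparound leakage is confined to the flagged edge region).
# Because the analytic signal is band-limited to [lo, hi], its envelope is
# recovered from a decimated inverse transform (rate fs/decim), which is
# where most of the speed of the band-power stage comes from.
# Returns list(env, fs_env): envelope samples at times (k-1) * decim / fs.
band_envelope <- function(x, fs, lo_hz, hi_hz, order = NULL) {
  b <- fir_bandpass_kernel(fs, lo_hz, hi_hz, order)
  h <- stats::convolve(b, rev(b), type = "open")
  n <- length(x); m <- length(h)
  # decimation factor: power of two keeping fs/decim comfortably above the
  # band's upper edge plus the transition width
  # the analytic signal is one-sided in [lo, hi (+ transition ~ lo)], so
  # complex sampling at fs/decim > hi + lo + 1 is alias-free
  decim <- 1L
  while (decim < 32L && fs / (2L * decim) >= hi_hz + lo_hz + 1)
    decim <- 2L * decim
  nfft <- 2L * decim * stats::nextn(ceiling((n + m - 1L) / (2L * decim)),
                                    c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  H <- stats::fft(c(h, numeric(nfft - m)))
  ns <- nfft %/% decim
  Y <- X[seq_len(ns)] * H[seq_len(ns)]
  mask <- numeric(ns)
  mask[c(1L, ns / 2 + 1L)] <- 1
  mask[2:(ns / 2)] <- 2
  z <- stats::fft(Y * mask, inverse = TRUE) / nfft   # == z[decim * k] of full
  delay <- (m - 1L) %/% 2L                           # integer group delay
  # sample indices of z correspond to original samples 1 + decim*(k-1);
  # shift by the kernel delay (delay is a multiple of 1 in original samples,
  # envelope is smooth so nearest decimated sample suffices)
  k0 <- delay %/% decim
  n_env <- ((n - 1L) %/% decim) + 1L
  env <- Mod(z[(k0 + 1L):(k0 + n_env)])
  list(env = env, fs_env = fs / decim, decim = decim)
}

#' Zero-phase FIR band-pass filtering of all EEG channels
#'
#' Applies a windowed-sinc (Hamming) band-pass, forward and backward in one
#' pass via the kernel autocorrelation, so the net filter has exactly zero
#' phase and the squared magnitude response of the design. Output length
#' equals input length; the first and last `filter_edge_s` seconds are where
#' edge transients live and downstream power estimation discards them.
#'
#' @param rec a `physio_recording`.
#' @param low_hz,high_hz cutoff frequencies (defaults 1 and 32 Hz).
#' @param order FIR order; default `ceiling(3 * fs / low_hz)`.
#' @return the recording with filtered EEG and an attribute
#'   `filter_edge_s` giving the edge-transient span in seconds.
#' @export
bandpass_eeg <- function(rec, low_hz = 1, high_hz = 32, order = NULL) {
  stopifnot(inherits(rec, "physio_recording"))
  if (rec$fs <= 2 * high_hz)
    stopf("sampling rate %g Hz must exceed twice the upper cutoff %g Hz",
          rec$fs, high_hz)
  b <- fir_bandpass_kernel(rec$fs, low_hz, high_hz, order)
  h <- stats::convolve(b, rev(b), type = "open")
  for (i in seq_len(nrow(rec$eeg)))
    rec$eeg[i, ] <- fft_conv_centered(rec$eeg[i, ], h)
  attr(rec, "filter_edge_s") <- (length(b) - 1) / rec$fs
  rec
}

#' Cut the paired pre/post analysis windows around one seizure
#'
#' The preictal window is the `window_len_s` seconds ending at clinical
#' onset, the postictal window the `window_len_s` seconds starting at
#' clinical offset; the ictal span itself is never analysed. An event
#' without enough data on either side is excluded with a reason rather
#' than truncated.
#'
#' @param rec a `physio_recording` (or anything with a known duration via
#'   `duration_s`).
#' @param annotation list or one-row data.frame with `onset_s`, `offset_s`.
#' @param window_len_s window length in seconds (default 600; the study also
#'   uses 420, 300, 180, 120, 60).
#' @param duration_s override record duration (seconds).
#' @return list of class `analysis_window_pair` with `preictal`,
#'   `postictal` (each `c(start_s, end_s)`), `window_len_s`, `event_id` —
#'   or, when excluded, a list with `excluded = TRUE` and `reason`.
#' @export
extract_windows <- function(rec, annotation, window_len_s = 600,
                            duration_s = NULL, event_id = "event") {
  on_s <- annotation$onset_s; off_s <- annotation$offset_s
  stopifnot(is.finite(on_s), is.finite(off_s), off_s > on_s)
  dur <- duration_s %||% (ncol(rec$eeg) / rec$fs)
  if (on_s < window_len_s)
    return(list(excluded = TRUE, event_id = event_id,
                reason = sprintf("only %.0f s before onset (< %.0f s window)",
                                 on_s, window_len_s)))
  if (dur - off_s < window_len_s)
    return(list(excluded = TRUE, event_id = event_id,
                reason = sprintf("only %.0f s after offset (< %.0f s window)",
                                 dur - off_s, window_len_s)))
  structure(list(preictal = c(on_s - window_len_s, on_s),
                 postictal = c(off_s, off_s + window_len_s),
                 window_len_s = window_len_s, event_id = event_id,
                 excluded = FALSE),
            class = "analysis_window_pair")
}

# slice a recording to a [start, end) time span
slice_recording <- function(rec, span) {
  i0 <- floor(span[1] * rec$fs) + 1L
  i1 <- floor(span[2] * rec$fs)
  physio_recording(rec$eeg[, i0:i1, drop = FALSE], rec$ecg[i0:i1], rec$fs,
                   rec$channel_labels, rec$montage_xy, rec$subject_id)
}
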