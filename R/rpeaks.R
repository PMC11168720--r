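# R-peak detection and RR-series construction

#' Detect R peaks in a single-lead ECG
#'
#' Pan-Tompkins-style detector: band-pass 5-15 Hz, five-point derivative,
#' squaring, 150 ms moving-window integration, then peak picking with an
#' adaptive signal/noise threshold and a 250 ms refractory period. Detected
#' fiducials are refined to the local extremum of the band-passed ECG.
#' Physiologically implausible rates (outside 20-220 bpm) are rejected at the
#' refractory/search stage.
#'
#' @param ecg numeric vector (millivolts).
#' @param fs sampling rate (Hz).
#' @return numeric vector of beat times in seconds (sample index - 1)/fs;
#'   empty, with a warning, when no QRS is detectable.
#' @export
detect_rpeaks <- function(ecg, fs) {
  n <- length(ecg)
  if (n < 10 * fs) stopf("need at least 10 s of ECG")
  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- as.numeric(signal::filtfilt(bp, ecg - mean(ecg)))
  d <- c(0, 0, diff(xf, lag = 4), 0, 0) / 4
  sq <- d * d
  mwi <- moving_average(sq, max(3L, round(0.15 * fs)))

  if (max(mwi) <= 0 || stats::sd(xf) == 0) {
    warning("no detectable QRS complexes", call. = FALSE)
    return(numeric(0))
  }
  # candidate local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(cand)) {
    warning("no detectable QRS complexes", call. = FALSE)
    return(numeric(0))
  }
  spki <- max(mwi[seq_len(min(n, 2L * fs))]) * 0.6
  npki <- mean(mwi[seq_len(min(n, 2L * fs))]) * 0.5
  thr <- npki + 0.25 * (spki - npki)
  refr <- round(0.25 * fs)
  peaks <- integer(0)
  last <- -refr
  for (i in cand) {
    if (i - last < refr) {
      # keep the larger of two competitors inside the refractory span
      if (length(peaks) && mwi[i] > mwi[peaks[length(peaks)]]) {
        peaks[length(peaks)] <- i
        last <- i
      }
      next
    }
    if (mwi[i] >= thr) {
      peaks <- c(peaks, i)
      last <- i
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
    thr <- npki + 0.25 * (spki - npki)
  }
  if (length(peaks) < 2L) {
    warning("no detectable QRS complexes", call. = FALSE)
    return(numeric(0))
  }
  # refine to the local |band-passed ECG| maximum near each integrator peak
  half <- round(0.10 * fs)
  ref <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    as.integer(lo + which.max(abs(xf[lo:hi])) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  # enforce plausible-rate bounds: drop beats closer than 60/220 s
  keep <- c(TRUE, diff(ref) > 60 / 220 * fs)
  ref <- ref[keep]
  (ref - 1L) / fs
}

#' Build an RR series from beat times
#'
#' @param beat_times_s strictly increasing beat times (seconds).
#' @return list of class `rr_series` with `beat_times_s`, `rr_s` (successive
#'   differences), and empty `rr4hz`/`t4hz` until [interpolate_rr()] is run.
#' @export
rr_series <- function(beat_times_s) {
  stopifnot(!is.unsorted(beat_times_s, strictly = TRUE))
  rr <- diff(beat_times_s)
  stopifnot(all(rr > 0))
  structure(list(beat_times_s = beat_times_s, rr_s = rr,
                 rr4hz = NULL, t4hz = NULL,
                 n_corrected = 0L, quality_warning = FALSE),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> %d beats, mean RR %.3f s (%.1f bpm)%s\n",
              length(x$beat_times_s), mean(x$rr_s), 60 / mean(x$rr_s),
              if (x$quality_warning) " [quality warning]" else ""))
  invisible(x)
}

#' Median-rule RR artifact correction
#'
#' Mirrors the published "medium" ectopic/artifact rule: an interval whose
#' deviation from the local median (11-beat centred window) exceeds
#' `threshold_s` is replaced by cubic-spline interpolation through the
#' surrounding accepted intervals. The number of RR samples never changes.
#' When more than `quality_frac` of intervals are corrected the output
#' carries a quality warning flag (e.g. bigeminy, where the rule is the
#' wrong model).
#'
#' @param rr an `rr_series`.
#' @param threshold_s deviation threshold in seconds (default 0.25).
#' @param window_beats local-median window (default 11).
#' @param quality_frac fraction of corrected beats that triggers the quality
#'   warning (default 0.2).
#' @return the corrected `rr_series` (fields `n_corrected`,
#'   `quality_warning` updated).
#' @export
correct_rr_artifacts <- function(rr, threshold_s = 0.25, window_beats = 11L,
                                 quality_frac = 0.2) {
  stopifnot(inherits(rr, "rr_series"))
  v <- rr$rr_s
  if (length(v) < 10L) stopf("need at least 10 RR intervals")
  k <- as.integer(window_beats) + (as.integer(window_beats) + 1L) %% 2L
  med <- stats::runmed(v, k, endrule = "median")
  bad <- abs(v - med) > threshold_s
  if (any(bad)) {
    idx <- seq_along(v)
    if (sum(!bad) >= 4L) {
      v[bad] <- stats::spline(idx[!bad], v[!bad], xout = idx[bad],
                              method = "natural")$y
    } else {
      v[bad] <- med[bad]
    }
    v <- pmax(v, 60 / 220)
  }
  rr$rr_s <- v
  rr$n_corrected <- sum(bad)
  rr$quality_warning <- mean(bad) > quality_frac
  if (rr$quality_warning)
    warnf("%.0f%% of RR intervals corrected - series quality is suspect",
          100 * mean(bad))
  rr
}

#' Cubic interpolation of the RR series onto a uniform 4 Hz grid
#'
#' Each interval is attached to the time of its closing beat; a cubic spline
#' through (beat time, RR) is evaluated on a 0.25 s grid spanning the beat
#' support.
#'
#' @param rr an `rr_series` with at least 4 beats.
#' @param fs_out output rate (default 4 Hz).
#' @return the `rr_series` with `rr4hz` and `t4hz` populated.
#' @export
interpolate_rr <- function(rr, fs_out = 4) {
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$beat_times_s) < 4L) stopf("need at least 4 beats to interpolate")
  tt <- rr$beat_times_s[-1L]
  step <- 1 / fs_out
  grid <- seq(ceiling(tt[1] / step) * step, floor(tt[length(tt)] / step) * step,
              by = step)
  rr$rr4hz <- stats::spline(tt, rr$rr_s, xout = grid, method = "fmm")$y
  rr$t4hz <- grid
  rr
}

#' Full ECG-to-RR preprocessing for one window
#'
#' Convenience chain: [detect_rpeaks()], [correct_rr_artifacts()],
#' [interpolate_rr()].
#'
#' @inheritParams detect_rpeaks
#' @param t0_s time of the first ECG sample in session coordinates.
#' @param ... passed to [correct_rr_artifacts()].
#' @return an `rr_series` with the 4 Hz series populated.
#' @export
ecg_to_rr <- function(ecg, fs, t0_s = 0, ...) {
  bt <- detect_rpeaks(ecg, fs)
  if (length(bt) < 4L) stopf("too few beats detected")
  interpolate_rr(correct_rr_artifacts(rr_series(bt + t0_s), ...))
}
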