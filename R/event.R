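# One seizure event: windows -> band power series -> coupling series

# resample a band_power_series onto a target grid (linear in power)
resample_bps <- function(bps, t_target) {
  p <- stats::approx(bps$t_s, bps$power, xout = t_target, rule = 1)$y
  if (anyNA(p)) stopf("target grid extends beyond the %s power series support",
                      bps$band$name)
  new_band_power_series(bps$band, t_target, p)
}

#' Band power series for one analysis window
#'
#' Cuts the window out of a recording, conditions the signals, and returns
#' EEG band power per channel plus HRV band power, all resampled onto one
#' shared integer-second grid (the alignment contract of the coupling
#' stage). Filter edge transients and the RR support boundary are excluded
#' by construction of the shared grid.
#'
#' @param rec a `physio_recording` (unfiltered; band filtering is applied
#'   per band here).
#' @param span `c(start_s, end_s)` of the window within the recording.
#' @param eeg_bands,hrv_bands band name subsets.
#' @param grid_step_s coarse grid step (default 1 s).
#' @param edge_pad_s guard seconds dropped at both window ends (default 5,
#'   covering the band filter edge and envelope smoothing).
#' @param hrv_method passed to [hrv_band_power()].
#' @return list: `t_s` (shared grid), `eeg` (nested list channel -> band ->
#'   `band_power_series`), `hrv` (band -> `band_power_series`), `rr`.
#' @export
window_band_power <- function(rec, span, eeg_bands = eeg_bands(),
                              hrv_bands = hrv_bands(), grid_step_s = 1,
                              edge_pad_s = 5, hrv_method = "spwvd") {
  win <- slice_recording(rec, span)
  rr <- ecg_to_rr(win$ecg, win$fs, t0_s = span[1])
  t_lo <- max(span[1] + edge_pad_s, ceiling(rr$t4hz[1]))
  t_hi <- min(span[2] - edge_pad_s, floor(rr$t4hz[length(rr$t4hz)]))
  if (t_hi - t_lo < 60) stopf("window too short after edge trimming")
  tg <- seq(t_lo, t_hi, by = grid_step_s)

  hrv <- lapply(hrv_bands, function(b) {
    bp <- hrv_band_power(rr$rr4hz, b, grid_step_s = grid_step_s,
                         t0_s = rr$t4hz[1], method = hrv_method)
    resample_bps(bp, tg)
  })
  names(hrv) <- hrv_bands

  eeg <- lapply(seq_len(nrow(win$eeg)), function(ch) {
    out <- lapply(eeg_bands, function(b) {
      bp <- eeg_band_power(win$eeg[ch, ], win$fs, b,
                           grid_step_s = grid_step_s, t0_s = span[1])
      resample_bps(bp, tg)
    })
    names(out) <- eeg_bands
    out
  })
  names(eeg) <- win$channel_labels
  list(t_s = tg, eeg = eeg, hrv = hrv, rr = rr,
       channel_labels = win$channel_labels)
}

#' All directional coupling series for one seizure event
#'
#' For every channel and every (EEG band, HRV band) pair, fits the
#' brain-to-heart and heart-to-brain sliding-window models in both analysis
#' windows: with the full four EEG bands and both HRV bands that is 16
#' coupling series per channel and phase (8 per direction).
#'
#' @param rec a `physio_recording`.
#' @param windows an `analysis_window_pair` from [extract_windows()].
#' @param eeg_bands,hrv_bands band subsets (defaults: all).
#' @param directions coupling directions to fit (default both).
#' @param window_s,step_s,lag_s estimator settings (see [bhi_fit()]).
#' @param grid_step_s coarse grid step (default 1 s).
#' @param hrv_method HRV power estimator.
#' @return long data.frame: `event_id`, `phase`, `channel`, `direction`,
#'   `eeg_band`, `hrv_band`, `t_s`, `coeff`, `other` (intercept or AR gain),
#'   `degenerate`, `resid_var`.
#' @export
compute_bhi_event <- function(rec, windows, eeg_bands = eeg_bands(),
                              hrv_bands = hrv_bands(),
                              directions = c("bth", "htb"),
                              window_s = 15, step_s = 1, lag_s = 1,
                              grid_step_s = 1, hrv_method = "spwvd") {
  stopifnot(inherits(windows, "analysis_window_pair"))
  if (isTRUE(windows$excluded)) stopf("event %s is excluded", windows$event_id)
  phases <- list(preictal = windows$preictal, postictal = windows$postictal)
  out <- vector("list", 2L * length(rec$channel_labels) *
                  length(eeg_bands) * length(hrv_bands) * 2L)
  ii <- 0L
  for (ph in names(phases)) {
    bp <- window_band_power(rec, phases[[ph]], eeg_bands, hrv_bands,
                            grid_step_s = grid_step_s, hrv_method = hrv_method)
    for (ch in bp$channel_labels) {
      for (eb in eeg_bands) for (hb in hrv_bands) {
        for (dr in directions) {
          f <- if (dr == "bth") {
            estimate_bth(bp$hrv[[hb]], bp$eeg[[ch]][[eb]],
                         window_s = window_s, step_s = step_s, lag_s = lag_s)
          } else {
            estimate_htb(bp$eeg[[ch]][[eb]], bp$hrv[[hb]],
                         window_s = window_s, step_s = step_s, lag_s = lag_s)
          }
          ii <- ii + 1L
          out[[ii]] <- data.frame(
            event_id = windows$event_id, phase = ph, channel = ch,
            direction = dr, eeg_band = eb, hrv_band = hb,
            t_s = f$t_s, coeff = f$coefficients[, "sdg"],
            other = f$coefficients[, 1L],
            degenerate = f$quality$degenerate,
            resid_var = f$quality$resid_var,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out[seq_len(ii)])
}

#' Phase summaries of one event's coupling series
#'
#' Median coupling coefficient per (phase, channel, direction, band pair)
#' over the whole window, plus per-one-minute medians for the trend
#' analysis.
#'
#' @param coeffs long data.frame from [compute_bhi_event()].
#' @param windows the event's `analysis_window_pair` (for minute edges).
#' @return list: `phase_median` (data.frame with `median_coeff`),
#'   `minute_median` (data.frame with `minute` index counted within phase,
#'   1 = earliest).
#' @export
event_phase_summary <- function(coeffs, windows) {
  grp <- c("event_id", "phase", "channel", "direction", "eeg_band", "hrv_band")
  ok <- !coeffs$degenerate & is.finite(coeffs$coeff)
  cc <- coeffs[ok, , drop = FALSE]
  phase_median <- stats::aggregate(cc["coeff"], cc[grp], stats::median)
  names(phase_median)[names(phase_median) == "coeff"] <- "median_coeff"

  start <- ifelse(cc$phase == "preictal", windows$preictal[1],
                  windows$postictal[1])
  cc$minute <- pmin(floor((cc$t_s - start) / 60) + 1L,
                    ceiling(windows$window_len_s / 60))
  minute_median <- stats::aggregate(cc["coeff"], cc[c(grp, "minute")],
                                    stats::median)
  names(minute_median)[names(minute_median) == "coeff"] <- "median_coeff"
  list(phase_median = phase_median, minute_median = minute_median)
}
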