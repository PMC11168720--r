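# Forward simulation of complete coupled EEG/ECG sessions with known,
# possibly phase-dependent coupling, for verification by parameter recovery.

#' Define a simulation scenario
#'
#' A scenario fixes every generative choice of [simulate_session()]: session
#' geometry (duration, seizure placement), the heartbeat side (reference
#' rate, baseline LF/HF modulation amplitudes), the EEG side (per-band AR
#' gains, baseline heart-to-brain couplings), noise levels, and the planted
#' pre/post coupling effect.
#'
#' Defaults emulate the study conditions: 10-minute windows either side of
#' a one-minute seizure, ~70 bpm with modulation depths giving normal
#' LF/HF variability, four-band EEG with amplitudes of tens of microvolts,
#' and a planted postictal drop of the heart-to-brain LF-to-delta coupling
#' to one third of its preictal level in a 10-channel patch.
#'
#' @param duration_s total session length; default fits 600 s windows plus a
#'   60 s ictal span and padding.
#' @param n_channels number of EEG channels (default 29, the reference
#'   montage).
#' @param fs sampling rate of the synthesized signals (default 64 Hz; the
#'   EEG content lives below 30 Hz).
#' @param hr_ref_bpm reference heart rate (default 70).
#' @param c_lf0,c_hf0 baseline LF/HF modulation amplitudes (default 0.03 /
#'   0.025, dimensionless fractional rate modulation).
#' @param eta per-EEG-band AR gains (default 0.85, 0.8, 0.8, 0.75).
#' @param htb_base baseline heart-to-brain coupling scale: chosen so
#'   equilibrium band amplitudes are ~10-25 microvolts given the HRV band
#'   powers in s^2.
#' @param bth_base baseline brain-to-heart coupling (modulation amplitude
#'   per microvolt^2 of EEG band power).
#' @param effect list describing the planted effect: `direction`
#'   (`"htb"`/`"bth"`), `hrv_band`, `eeg_band`, `channels` (labels or
#'   indices),
#'   `post_factor` (multiplier applied postictally; 1 = null). `NULL` for a
#'   null scenario.
#' @param eeg_noise_uV additive white EEG noise s.d. (default 1).
#' @param a_sd,c_sd stationary s.d. of the slow AR(1) fluctuations injected
#'   into the band-amplitude and modulation-amplitude dynamics (defaults
#'   2 microvolts and 0.005). These are the physiological ongoing
#'   fluctuations that make the inverse problem identifiable; set to 0 for
#'   the deterministic decoupled limit.
#' @param rr_jitter_s beat-time jitter s.d. (default 0.003).
#' @param event_jitter_sd lognormal s.d. of per-event coupling variation
#'   (default 0.1).
#' @param onset_s,offset_s seizure span (defaults 660 s and 720 s).
#' @param window_len_s analysis window length (default 600).
#' @param eeg_bands,hrv_bands band subsets to synthesize/analyse (defaults:
#'   all four EEG bands, both HRV bands). Restricting them speeds up large
#'   cohort simulations.
#' @param ipfm_dt IPFM integrator step (default 1/fs).
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(duration_s = NULL, n_channels = 29L, fs = 64,
                         hr_ref_bpm = 70, c_lf0 = 0.03, c_hf0 = 0.025,
                         eta = c(delta = 0.85, theta = 0.8, alpha = 0.8,
                                 beta = 0.75),
                         htb_base = NULL, bth_base = 5e-6,
                         effect = list(direction = "htb", hrv_band = "LF",
                                       eeg_band = "delta",
                                       channels = c("C3", "C4", "Cz", "Fz",
                                                    "Pz", "Fc1", "Fc2",
                                                    "Cp1", "Cp2", "P3"),
                                       post_factor = 1 / 3),
                         eeg_noise_uV = 1, a_sd = 2, c_sd = 0.005,
                         rr_jitter_s = 0.003,
                         event_jitter_sd = 0.1,
                         onset_s = NULL, offset_s = NULL,
                         window_len_s = 600,
                         eeg_bands = c("delta", "theta", "alpha", "beta"),
                         hrv_bands = c("LF", "HF"),
                         ipfm_dt = NULL) {
  onset_s <- onset_s %||% (window_len_s + 60)
  offset_s <- offset_s %||% (onset_s + 60)
  duration_s <- duration_s %||% (offset_s + window_len_s + 60)
  stopifnot(duration_s >= offset_s + window_len_s,
            onset_s >= window_len_s, all(abs(eta) < 1))
  # equilibrium amplitude a_eq = sdg * P_i / (1 - eta); P_LF ~ c_lf0^2/2
  if (is.null(htb_base)) {
    p_ref <- c(LF = c_lf0^2 / 2, HF = c_hf0^2 / 2)
    # joint equilibrium band amplitude ~15 uV with both HRV bands driving
    htb_base <- outer(1 - eta, 1 / p_ref) * 15 / length(p_ref)
    dimnames(htb_base) <- list(names(eta), names(p_ref))
  }
  structure(list(duration_s = duration_s, n_channels = as.integer(n_channels),
                 fs = fs, hr_ref_bpm = hr_ref_bpm, c_lf0 = c_lf0,
                 c_hf0 = c_hf0, eta = eta, htb_base = htb_base,
                 bth_base = bth_base, effect = effect,
                 eeg_noise_uV = eeg_noise_uV, a_sd = a_sd, c_sd = c_sd,
                 rr_jitter_s = rr_jitter_s,
                 event_jitter_sd = event_jitter_sd,
                 onset_s = onset_s, offset_s = offset_s,
                 window_len_s = window_len_s,
                 eeg_bands = eeg_bands, hrv_bands = hrv_bands,
                 ipfm_dt = ipfm_dt %||% (1 / fs)),
            class = "sim_scenario")
}

#' Forward-simulate one coupled EEG/ECG session
#'
#' Runs the generative model forward on a 1 s grid: HRV modulation
#' amplitudes carry baseline tones plus brain-to-heart drive from EEG band
#' power; per-channel EEG band amplitudes follow the exogenous
#' autoregression driven by HRV band power; beats come from the IPFM
#' integrator over the two-tone modulation; the ECG is rendered as a
#' Mexican-hat QRS pulse train at the beat times; the EEG is the sum of
#' band carriers at the band centre frequencies plus white noise. During
#' the ictal span a broadband high-amplitude burst is added (the analysis
#' never uses that span). The planted effect multiplies the chosen coupling
#' by `post_factor` from seizure offset onward.
#'
#' @param scenario a `sim_scenario`.
#' @param seed RNG seed; identical (scenario, seed) gives identical output.
#' @return list of class `sim_output`: `recording` (a `physio_recording`),
#'   `annotations` (data.frame), `truth` (list of ground-truth coefficient
#'   series and per-event coupling values), `scenario`.
#' @export
simulate_session <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  set.seed(seed)
  dt <- 1
  n <- ceiling(sc$duration_s / dt) + 1L
  tg <- (seq_len(n) - 1) * dt
  nch <- sc$n_channels
  labels <- montage_labels()[seq_len(nch)]
  ebands <- sc$eeg_bands; hbands <- sc$hrv_bands
  jit <- function() exp(stats::rnorm(1, 0, sc$event_jitter_sd))

  # per-event realized couplings (jittered baselines)
  htb <- array(rep(sc$htb_base[ebands, hbands, drop = FALSE], each = nch),
               dim = c(nch, length(ebands), length(hbands)),
               dimnames = list(labels, ebands, hbands))
  htb <- htb * exp(stats::rnorm(length(htb), 0, sc$event_jitter_sd))
  bth <- matrix(sc$bth_base * exp(stats::rnorm(length(ebands) * length(hbands),
                                               0, sc$event_jitter_sd)),
                length(ebands), length(hbands),
                dimnames = list(ebands, hbands))
  eta_ch <- matrix(rep(sc$eta[ebands], each = nch), nch, length(ebands),
                   dimnames = list(labels, ebands)) *
    exp(stats::rnorm(nch * length(ebands), 0, sc$event_jitter_sd / 4))
  eta_ch <- pmin(eta_ch, 0.92)   # keep the closed brain-heart loop stable
  hr <- sc$hr_ref_bpm * jit()

  # postictal multiplier per (channel, eeg band, hrv band)
  post_fac <- array(1, dim = dim(htb), dimnames = dimnames(htb))
  bth_post <- matrix(1, length(ebands), length(hbands),
                     dimnames = dimnames(bth))
  ef <- sc$effect
  has_effect <- !is.null(ef) && !isTRUE(all.equal(ef$post_factor, 1))
  if (has_effect) {
    if (ef$direction == "htb") {
      chs <- if (is.character(ef$channels)) {
        which(labels %in% ef$channels)
      } else intersect(ef$channels, seq_len(nch))
      post_fac[chs, ef$eeg_band, ef$hrv_band] <- ef$post_factor
    } else {
      bth_post[ef$eeg_band, ef$hrv_band] <- ef$post_factor
    }
  }
  postk <- tg >= sc$offset_s    # effect switches at seizure offset

  # grid-level difference equations (noise enters via the signal render)
  c_i <- matrix(0, n, length(hbands), dimnames = list(NULL, hbands))
  c_i[1, ] <- c(LF = sc$c_lf0, HF = sc$c_hf0)[hbands]
  a <- array(0, dim = c(n, nch, length(ebands)),
             dimnames = list(NULL, labels, ebands))
  a[1, , ] <- 10
  c0v <- c(LF = sc$c_lf0, HF = sc$c_hf0)[hbands]
  drive_ch <- 1L   # EEG driver channel for the brain-to-heart side
  # slow AR(1) physiological fluctuations driving both sides
  ar1 <- function(n, phi, sd_stat) {
    if (sd_stat <= 0) return(numeric(n))
    as.numeric(stats::filter(stats::rnorm(n, 0, sd_stat * sqrt(1 - phi^2)),
                             phi, "recursive"))
  }
  ne <- length(ebands); nh <- length(hbands)
  eps_a <- array(0, dim = c(n, nch, ne))
  for (ch in seq_len(nch)) for (j in seq_len(ne))
    eps_a[, ch, j] <- ar1(n, 0.7, sc$a_sd)
  eps_c <- vapply(seq_len(nh), function(i) ar1(n, 0.9, sc$c_sd),
                  numeric(n))
  for (k in 2:n) {
    p_i_prev <- c_i[k - 1, ]^2 / 2
    p_b_prev <- a[k - 1, drive_ch, ]^2 / 2
    for (j in seq_along(ebands)) {
      fac <- if (postk[k]) matrix(post_fac[, j, ], nch, nh)
             else matrix(1, nch, nh)
      hmat <- matrix(htb[, j, ], nch, nh)
      drive <- (hmat * fac) %*% p_i_prev
      a[k, , j] <- pmax(eta_ch[, j] * a[k - 1, , j] + drive + eps_a[k, , j],
                        0.5)
    }
    for (i in seq_along(hbands)) {
      bfac <- if (postk[k]) bth_post[, i] else rep(1, length(ebands))
      # one EEG band drives each HRV band (delta->LF, theta->HF pairing)
      jb <- if (hbands[i] == "LF") 1L else min(2L, length(ebands))
      c_i[k, i] <- pmax(c0v[i] + bth[jb, i] * bfac[jb] * p_b_prev[jb] +
                          eps_c[k, i], 0)
    }
  }

  if (!all(is.finite(c_i)) || max(rowSums(abs(c_i))) >= 0.95)
    stopf(paste("coupling gains drive the autonomic modulation towards the",
                "IPFM validity limit (|m| -> 1); reduce bth_base/htb_base"))

  # render continuous signals
  fs <- sc$fs
  ns <- round(sc$duration_s * fs)
  ts <- (seq_len(ns) - 1) / fs
  omega <- vapply(ebands, function(b) band_definition(b)$omega_center, 0)
  phases <- stats::runif(nch * length(ebands), 0, 2 * pi)
  eeg <- matrix(0, nch, ns)
  for (j in seq_along(ebands)) {
    amp <- apply(a[, , j, drop = FALSE][, , 1], 2, function(v)
      stats::approx(tg, v, xout = ts, rule = 2)$y)  # ns x nch
    ph <- matrix(phases[((j - 1) * nch + 1):(j * nch)], nch, 1)
    eeg <- eeg + t(amp) * sin(outer(rep(omega[j], nch), ts) + ph[, 1])
  }
  eeg <- eeg + matrix(stats::rnorm(nch * ns, 0, sc$eeg_noise_uV), nch, ns)
  # ictal burst: broadband noise, detector-hostile
  ict <- ts >= sc$onset_s & ts <= sc$offset_s
  if (any(ict))
    eeg[, ict] <- eeg[, ict] + matrix(stats::rnorm(nch * sum(ict), 0, 40),
                                      nch, sum(ict))

  omega_lf <- band_definition("LF")$omega_center
  omega_hf <- band_definition("HF")$omega_center
  m <- modulation_from_eq1(
    if ("LF" %in% hbands) c_i[, "LF"] else rep(0, n),
    if ("HF" %in% hbands) c_i[, "HF"] else rep(0, n), tg)
  beats <- ipfm_generate(m, hr, sc$duration_s, dt = sc$ipfm_dt)
  if (sc$rr_jitter_s > 0) {
    beats <- sort(beats + stats::rnorm(length(beats), 0, sc$rr_jitter_s))
    beats <- beats[beats > 0 & beats < sc$duration_s]
  }
  ecg <- render_ecg(beats, fs, ns)
  if (any(ict)) ecg[ict] <- ecg[ict] + stats::rnorm(sum(ict), 0, 0.2)

  rec <- physio_recording(eeg, ecg, fs, labels, subject_id = sprintf("sim%03d", seed))
  structure(list(
    recording = rec,
    annotations = data.frame(onset_s = sc$onset_s, offset_s = sc$offset_s),
    truth = list(t_s = tg, a = a, c_i = c_i, htb = htb, bth = bth,
                 eta = eta_ch, post_fac = post_fac, bth_post = bth_post,
                 beats = beats, hr_ref_bpm = hr),
    scenario = sc, seed = seed), class = "sim_output")
}

# Mexican-hat (negative second derivative of a Gaussian) QRS template,
# sigma ~ 12 ms: a single dominant positive R peak per beat
render_ecg <- function(beat_times_s, fs, n_samples, sigma_s = 0.012,
                       amp_mV = 1) {
  tpl_half <- round(5 * sigma_s * fs)
  tt <- (-tpl_half:tpl_half) / fs
  tpl <- amp_mV * (1 - (tt / sigma_s)^2) * exp(-tt^2 / (2 * sigma_s^2))
  ecg <- numeric(n_samples)
  idx <- round(beat_times_s * fs) + 1L
  for (k in seq_along(idx)) {
    i0 <- idx[k] - tpl_half; i1 <- idx[k] + tpl_half
    sel <- max(1L, i0):min(n_samples, i1)
    ecg[sel] <- ecg[sel] + tpl[sel - i0 + 1L]
  }
  ecg + stats::rnorm(n_samples, 0, 0.01)
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> seed %d: %s, seizure %g-%g s, %d beats\n",
              x$seed, format(x$recording$subject_id),
              x$annotations$onset_s[1], x$annotations$offset_s[1],
              length(x$truth$beats)))
  invisible(x)
}

#' Simulate a cohort of seizure events
#'
#' Independent sessions from a shared scenario template with per-event
#' random baseline variation (couplings, heart rate, phases). `null_mode`
#' removes the planted pre/post effect for calibration studies.
#'
#' @param n_events number of events (default 38, the study cohort size;
#'   fewer than 6 is refused since the paired test needs 6 pairs).
#' @param scenario a `sim_scenario` template.
#' @param seed cohort seed; event e uses seed `seed * 1000 + e`.
#' @param null_mode logical; `TRUE` forces `post_factor = 1`.
#' @return list of `sim_output` objects.
#' @export
simulate_cohort <- function(n_events = 38L, scenario = sim_scenario(),
                            seed = 1L, null_mode = FALSE) {
  if (n_events < 6L) stopf("need at least 6 events for the paired analysis")
  if (null_mode && !is.null(scenario$effect)) scenario$effect$post_factor <- 1
  lapply(seq_len(n_events), function(e)
    simulate_session(scenario, seed = seed * 1000L + e))
}

#' Write a simulated session to EDF + annotation text
#'
#' Round-trip fixture writer: emits the EDF dialect the reader consumes.
#'
#' @param sim a `sim_output`.
#' @param dir output directory.
#' @param stem file stem (default the subject id).
#' @return named character vector with paths `edf` and `annotations`.
#' @export
write_session <- function(sim, dir, stem = NULL) {
  stopifnot(inherits(sim, "sim_output"))
  stem <- stem %||% sim$recording$subject_id
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edf_path <- file.path(dir, paste0(stem, ".edf"))
  ann_path <- file.path(dir, paste0(stem, "_annotations.txt"))
  rec <- sim$recording
  write_edf(edf_path,
            rbind(rec$eeg, rec$ecg), rec$fs,
            c(paste("EEG", rec$channel_labels), "ECG"),
            units = c(rep("uV", nrow(rec$eeg)), "mV"))
  writeLines(c("# onset_s offset_s",
               sprintf("%.3f %.3f", sim$annotations$onset_s,
                       sim$annotations$offset_s)), ann_path)
  c(edf = edf_path, annotations = ann_path)
}
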