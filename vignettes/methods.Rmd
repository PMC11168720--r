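---
title: "Methods: directional brain-heart coupling estimation and its verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional brain-heart coupling estimation and its verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the generative model behind `bhisdg`, the
estimators that invert it, the statistical pipeline, and — importantly —
what the synthetic-data verification does and does not establish.

## The generative model

Two physiologically motivated equations tie heartbeat dynamics and
cortical band amplitudes together on a coarse analysis grid (1 s by
default).

**Heartbeats.** An integral pulse frequency modulation (IPFM) generator
integrates the instantaneous rate `(hr_ref/60)(1 + m(t))` and emits a beat
at every integer crossing. The modulation is two-tone,
`m(t) = C_LF(t) sin(ω_LF t) + C_HF(t) sin(ω_HF t)`, with carriers at the
LF/HF band centres (0.095 and 0.275 Hz). An RR series generated this way
carries its autonomic drive as tone amplitudes: a tone of amplitude `C`
contributes band power `C²/2`, which fixes the amplitude convention
`C = sqrt(2 · P)` used everywhere in the package.

**Cortical amplitudes.** Each EEG channel is modelled as a sum of four
band carriers, `EEG(t) = Σ_j a_j(t) sin(ω_j t + φ_j)`, with the band
amplitude following an exogenous autoregression driven by lagged HRV band
power. The carrier phases never enter the coupling estimates (the fits are
in the amplitude domain), which is why the estimator ignores them.

**Coupling.** The brain-to-heart direction makes the modulation amplitude
a linear function of lagged EEG band power (`C_i = C_i0 + SDG·P_brain`);
the heart-to-brain direction adds the lagged HRV band power as an
exogenous regressor to the amplitude autoregression
(`a_j = η a_j⁻ + SDG·P_i⁻`). The coefficients have mixed physical units
(e.g. seconds per microvolt²); all group statistics are rank- or z-based,
so only contrasts matter.

## Estimation choices

* **Lag.** The model text leaves the lag between driver and response as
  "the preceding instant"; we fix it to one grid step (1 s), matching the
  grid on which band powers are defined. It is configurable (`lag_s`).
* **Sliding window 15 s, step 1 s.** Ten points is the hard identifiability
  floor for a two-parameter fit; 15 gives a margin while staying
  time-resolved. Windows are solved by closed-form OLS on rolling sums;
  each estimate is assigned to the window centre. The 1-min trend
  summaries then take medians of whatever falls inside each minute.
* **Degeneracy.** A window whose design is ill-conditioned on the
  column-normalised scale (e.g. constant driver power) yields `NA`
  coefficients plus a quality flag — never an extrapolated value. When only
  the driver is degenerate (no cardiac drive), the AR gain is still
  reported.
* **Negative couplings are retained.** The comparison statistics are
  nonparametric and two-sided, so sign information is preserved.

## Band power

* **EEG**: zero-phase windowed-sinc (Hamming) band-pass — applied as one
  convolution with the kernel autocorrelation, so the response is exactly
  zero-phase — followed by the analytic-signal envelope. Power is
  `envelope²/2` smoothed over one grid step, so a pure in-band tone of
  amplitude A reads `A²/2`. The kernel order is ~3 cycles of the band's
  lower edge (rounded to a multiple of 32 so the group delay is exact
  under envelope decimation). Since the analytic signal is band-limited,
  its inverse transform is evaluated at a decimated rate — a pure
  efficiency device with no effect on the grid-sampled power (the
  tone-recovery tests pin this down).
* **HRV**: smoothed pseudo-Wigner–Ville distribution of the mean-removed
  4 Hz RR series, with independent time (5 s Hamming) and frequency
  (~0.015 Hz lag-window) smoothing, integrated over the LF or HF band per
  grid point and normalised so a tone again reads `A²/2`. A sliding Welch
  estimator is available (`method = "welch"`) as an independent
  cross-check; the two agree on stationary tones to within their smoothing
  differences.
* Filter edge transients: the shared analysis grid for a window starts and
  ends `edge_pad_s = 5` s inside it, and within the RR support, so neither
  filter edges nor interpolation boundaries reach the regressions.

## Preprocessing

The EEG conditioning filter is 1–32 Hz, zero phase. R peaks come from a
Pan–Tompkins-style detector (5–15 Hz band-pass, derivative, squaring,
150 ms integration, adaptive threshold, 250 ms refractory period, peak
refinement on the filtered ECG); the reference software used in the field
is proprietary, so this standard open detector is substituted and
validated on pulse-train fixtures (100% recovery within ±1 sample at
20 dB SNR in the suite). RR artifact correction mirrors the published
"medium" rule: intervals deviating more than 0.25 s from an 11-beat local
median are replaced by cubic-spline interpolation; if more than 20% of
beats are corrected the series is flagged (alternating bigeminy-like
rhythms are the intended catch — the rule is the wrong model there, and
the flag says so). The RR series is cubic-resampled at 4 Hz. Analysis
windows are the `window_len_s` seconds ending at clinical onset and
starting at clinical offset; events without enough data on either side are
excluded with a logged reason, never truncated.

## Group statistics

* **Normality screen**: Shapiro–Wilk per channel at 0.05; if a majority
  reject, the nonparametric branch is recommended (it is always what the
  maps use).
* **Wilcoxon signed-rank**, two-sided, zeros dropped. For n ≤ 25 the null
  distribution of W⁺ is computed exactly by the sign-flip generating
  function, which remains exact under tied ranks (base R's exact path
  refuses ties; the test suite checks our p-values against full 2ⁿ
  enumeration and against `wilcox.test` where both apply). Beyond n = 25 a
  normal approximation with tie and continuity correction is used.
* **Cluster correction**: connected components of raw-significant channels
  (α = 0.01) with size < 2 are discarded; surviving clusters are kept when
  their channel count exceeds the permutation null of the maximum cluster
  size, built from within-event pre/post label swaps (sign flips),
  1000 permutations by default, positive and negative clusters formed
  separately. The cluster statistic is *size* (channel count), following
  the "cluster size" language of the method being implemented, not cluster
  mass. Adjacency is distance-based — neighbours within 2.0× the median
  nearest-neighbour spacing of the montage — the standard sensor-space
  neighbourhood rule; a Delaunay triangulation would be the usual
  alternative, but no installed triangulation backend was available, and
  the distance rule is equally conventional. The factor 2.0 makes
  neighbouring outer-ring electrodes (F7–T3) adjacent while keeping the
  graph local (degrees 4–8 on the 29-channel montage).
* **Trends**: each event's per-minute medians — ten preictal plus ten
  postictal for the 10-minute setting — are z-scored jointly across the 20
  values and averaged across events per minute. Pooling both phases in one
  z-score is a deliberate reading of an ambiguous description: the stated
  aim is cross-seizure comparability of the pre-to-post transition, which
  per-phase z-scoring would erase (it would force both phases to mean
  zero). The per-phase variant remains available by splitting the matrix.

## The synthetic-data generator

`simulate_session()` runs the full generative chain: grid-level coupling
difference equations (with slow AR(1) physiological fluctuations of band
amplitudes, s.d. 2 µV, and modulation amplitudes, s.d. 0.005 — without
ongoing fluctuations the drivers settle to equilibrium and the inverse
problem loses excitation), IPFM beats integrated at the recording rate,
a Mexican-hat QRS pulse train with beat-time jitter, band carriers plus
white noise for the EEG, an ictal burst segment that the analysis must
exclude, and per-event lognormal variation of couplings and heart rate.
Default scenario values: 70 bpm, baseline modulation amplitudes 0.03 (LF)
and 0.025 (HF), AR gains 0.85/0.8/0.8/0.75 for δ/θ/α/β, heart-to-brain
gains scaled so equilibrium band amplitudes are ~15 µV, and a planted
postictal drop of the HtB LF→δ coupling to one third in a ten-channel
central patch (C3, C4, Cz, Fz, Pz, Fc1, Fc2, Cp1, Cp2, P3). The planted
pattern mirrors the kind of effect the pipeline is meant to find:
generalized-to-central HtB LF differences with preictal values higher.
Published example levels for such a drop ("0.6 to 0.2") are not
unit-consistent with RR power in s² and EEG in microvolts, so the defaults
keep the 3× contrast at unit-consistent magnitudes; the rank-based
statistics depend only on the contrast.

What the simulator does *not* emulate: realistic EEG background spectra
(1/f, spindles, artifacts), ECG morphology beyond the R wave, respiration,
volume conduction (channels are driven by a shared heart but have
independent amplitude noise), or nonstationary seizure dynamics beyond a
broadband burst. Passing the end-to-end tests therefore shows the pipeline
recovers the model's own couplings through signal rendering, detection and
estimation — it does not certify performance on real scalp data, where
estimator bias from non-sinusoidal oscillations and artifacts is untested.

## Numerical details

* IPFM integration is trapezoidal at the recording step with linear
  interpolation of threshold crossings; with `m ≡ 0` beats are exact to
  ~1e-12.
* The closed brain-heart loop in the simulator is quadratic (power feeds
  amplitude feeds power); gains are chosen to keep the loop contraction
  factor well below one, and the simulator refuses scenarios whose
  modulation approaches the IPFM validity limit `|m| → 1`.
* Rolling OLS uses cumulative sums in double precision; the noiseless
  recovery tests demand 1e-9 relative accuracy, well inside what the 15-
  to 60-point windows give.
* Permutation p-values use the add-one convention `(1 + #{null ≥ obs}) /
  (1 + n_perm)`; fewer than 100 permutations are refused.

## Verification sizes

The suite verifies: forward–inverse consistency at n = 400 grid points
(noiseless ≤ 1e-6 relative; 100 seeds at 20 dB SNR, median error ≤ 10%);
family-wise error of the corrected maps over 200 null cohorts of 38
events × 29 channels at 200 permutations; and planted-effect recovery
over 20 seeded end-to-end runs of 20-event cohorts (10-minute windows,
δ/LF bands, 29 channels at 64 Hz), with a 3-run replication at 5-minute
windows. The cohort size and permutation count for the end-to-end runs
are the package's chosen verification scale; the statistical conditions
(α = 0.01, minimum cluster 2, paired design) are those of the analysis
itself.

## Known limitations

* The exact internals of the proprietary RR-cleaning software being
  mirrored are unpublished; the median rule here is an approximation with
  a configurable threshold.
* Coupling estimates inherit the smoothing of the band-power estimators:
  through the full signal chain the estimated coefficients are attenuated
  relative to the generative values (errors-in-variables), which leaves
  pre/post contrasts intact — the tests check contrasts, not absolute
  end-to-end calibration.
* The cluster statistic (size) saturates at the true effect extent; with
  strongly spatially correlated noise a mass statistic would have more
  power. Size is used deliberately to match the implemented method.
* Ictal-phase coupling is out of scope; the ictal span is excluded by
  construction.
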