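# Forward half of the coupling framework: IPFM heartbeat synthesis, the
# two-tone autonomic modulation, and the grid-level difference equations.

#' Integral pulse frequency modulation heartbeat generator
#'
#' Integrates the instantaneous rate \eqn{(hr_{ref}/60)(1 + m(t))} and emits
#' a beat each time the integral crosses an integer (threshold crossings
#' located by linear interpolation), restarting implicitly. With no
#' modulation the generator is exact: beats every \eqn{60/hr_{ref}} seconds.
#'
#' @param m modulation: function of time or a vector sampled at `1/dt` Hz.
#' @param hr_ref_bpm reference heart rate (20-220).
#' @param duration_s length of the generated session.
#' @param dt integrator step in seconds (default 1/512, the recording rate).
#' @return beat times in seconds (first beat after time 0).
#' @export
ipfm_generate <- function(m, hr_ref_bpm, duration_s, dt = 1 / 512) {
  stopifnot(hr_ref_bpm > 20, hr_ref_bpm < 220, duration_s > 0)
  tt <- seq(0, duration_s, by = dt)
  mv <- if (is.function(m)) m(tt) else {
    if (length(m) < length(tt)) stopf("sampled modulation shorter than duration")
    m[seq_along(tt)]
  }
  rate <- (hr_ref_bpm / 60) * (1 + mv)
  if (any(rate <= 0)) stopf("modulation drives instantaneous rate <= 0")
  # trapezoidal cumulative integral of the rate
  I <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))
  nb <- floor(I[length(I)])
  if (nb < 1L) return(numeric(0))
  ks <- seq_len(nb)
  i0 <- findInterval(ks, I)            # I[i0] <= k < I[i0+1]
  ok <- i0 >= 1L & i0 < length(I)
  ks <- ks[ok]; i0 <- i0[ok]
  frac <- (ks - I[i0]) / (I[i0 + 1L] - I[i0])
  tt[i0] + frac * dt
}

#' Two-tone autonomic modulation with time-varying amplitudes
#'
#' \eqn{m(t) = C_{LF}(t)\sin(\omega_{LF} t) + C_{HF}(t)\sin(\omega_{HF} t)},
#' with the band amplitudes given on a coarse grid and held/interpolated to
#' the integrator step.
#'
#' @param c_lf,c_hf nonnegative amplitude series on the grid `t_grid`.
#' @param t_grid coarse time grid (seconds).
#' @param omega_lf,omega_hf angular carrier frequencies; defaults are the
#'   band centres (2*pi*0.095, 2*pi*0.275).
#' @return function of time, vectorised, usable as `m` in [ipfm_generate()].
#' @export
modulation_from_eq1 <- function(c_lf, c_hf, t_grid,
                                omega_lf = band_definition("LF")$omega_center,
                                omega_hf = band_definition("HF")$omega_center) {
  stopifnot(length(c_lf) == length(t_grid), length(c_hf) == length(t_grid))
  if (any(c_lf < 0) || any(c_hf < 0)) stopf("modulation amplitudes must be nonnegative")
  flf <- stats::approxfun(t_grid, c_lf, rule = 2)
  fhf <- stats::approxfun(t_grid, c_hf, rule = 2)
  function(t) flf(t) * sin(omega_lf * t) + fhf(t) * sin(omega_hf * t)
}

#' Run the coupling difference equations forward on the analysis grid
#'
#' The series-level forward model, the exact counterpart of what
#' [bhi_fit()] inverts:
#' brain-to-heart \eqn{C_i(k) = C_{i0} + SDG_{b2h}(k) P_{brain}(k-1) + e_C(k)},
#' heart-to-brain \eqn{a_j(k) = \eta a_j(k-1) + SDG_{h2b}(k) P_i(k-1) + e_a(k)},
#' with \eqn{P_i(k) = C_i(k)^2/2} and \eqn{P_{brain}(k) = a_j(k)^2/2}
#' closing the loop (tone-power convention). Noise-free with the default
#' zero noise levels, which is what the forward-inverse consistency oracle
#' requires.
#'
#' @param n number of grid points.
#' @param sdg_bth,sdg_htb coupling coefficients: scalars or length-`n` series.
#' @param eta AR gain of the EEG band amplitude (|eta| < 1).
#' @param c0 baseline HRV modulation amplitude.
#' @param a0 initial EEG band amplitude.
#' @param p_brain optional exogenous EEG band power series (length `n`);
#'   when supplied the brain side is not fed back from `a`.
#' @param p_i optional exogenous HRV band power series.
#' @param noise_c,noise_a Gaussian innovation standard deviations (default 0).
#' @return list with series `a`, `c_i`, `p_brain`, `p_i` (all length `n`)
#'   and the true coefficient series.
#' @export
sdg_forward <- function(n, sdg_bth, sdg_htb, eta, c0 = 0.03, a0 = 10,
                        p_brain = NULL, p_i = NULL,
                        noise_c = 0, noise_a = 0) {
  if (abs(eta) >= 1) stopf("|eta| >= 1 gives an unstable EEG amplitude process")
  sb <- rep_len(sdg_bth, n); sh <- rep_len(sdg_htb, n)
  a <- numeric(n); ci <- numeric(n)
  ext_b <- !is.null(p_brain); ext_i <- !is.null(p_i)
  pb <- if (ext_b) rep_len(p_brain, n) else numeric(n)
  pi_ <- if (ext_i) rep_len(p_i, n) else numeric(n)
  a[1] <- a0
  ci[1] <- c0
  if (!ext_b) pb[1] <- a[1]^2 / 2
  if (!ext_i) pi_[1] <- ci[1]^2 / 2
  ec <- stats::rnorm(n, 0, noise_c); ea <- stats::rnorm(n, 0, noise_a)
  for (k in 2:n) {
    a[k] <- eta * a[k - 1] + sh[k] * pi_[k - 1] + ea[k]
    ci[k] <- c0 + sb[k] * pb[k - 1] + ec[k]
    if (!ext_b) pb[k] <- a[k]^2 / 2
    if (!ext_i) pi_[k] <- ci[k]^2 / 2
  }
  list(a = a, c_i = ci, p_brain = pb, p_i = pi_,
       sdg_bth = sb, sdg_htb = sh, eta = eta, c0 = c0)
}
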