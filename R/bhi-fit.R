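#' Time-resolved directional brain-heart coupling by sliding-window least squares
#'
#' Fits, per sliding window, one of the two directional coupling models on a
#' common coarse time grid (step `dt`):
#' \describe{
#'   \item{brain-to-heart (`"bth"`)}{\eqn{C_i(k) = C_{i0} + SDG \cdot
#'     P_{brain}(k - \ell) + e(k)} — the HRV-band modulation amplitude
#'     regressed on lagged EEG band power, with intercept.}
#'   \item{heart-to-brain (`"htb"`)}{\eqn{a_j(k) = \eta\, a_j(k - \ell) +
#'     SDG \cdot P_i(k - \ell) + e(k)} — the EEG band amplitude as an
#'     exogenous autoregression on its own past and lagged HRV band power,
#'     no intercept.}
#' }
#' Ordinary least squares is solved in closed form per window from rolling
#' sums; each coefficient pair is assigned to the window centre. Windows with
#' a degenerate or ill-conditioned design (e.g. constant driver power) yield
#' `NA` coefficients and a quality flag instead of fabricated values.
#'
#' @param response numeric vector: HRV modulation amplitude \eqn{C_i}
#'   (`"bth"`) or EEG band amplitude \eqn{a_j} (`"htb"`).
#' @param driver numeric vector, same grid: lagging regressor power series
#'   (\eqn{P_{brain}} or \eqn{P_i}).
#' @param t_s time grid (uniform); default `seq_along(response) - 1`.
#' @param direction `"bth"` or `"htb"`.
#' @param window_s sliding-window length in seconds (default 15).
#' @param step_s window step (default 1).
#' @param lag_s driver lag \eqn{\ell} in seconds (default one grid step).
#' @param cond_max condition-number flag threshold (default 1e8).
#' @return object of class `bhi_fit`: list with `t_s` (window centres),
#'   `coefficients` (matrix, columns `c0`/`eta` and `sdg`), `quality`
#'   (data.frame: `resid_var`, `cond`, `degenerate`), plus the settings.
#' @seealso [estimate_bth()], [estimate_htb()], [simulate.bhi_fit()]
#' @examples
#' set.seed(1)
#' p <- 1 + runif(300)
#' y <- 2 + 0.3 * c(NA, p[-300]); y[1] <- 2
#' f <- bhi_fit(y, p, direction = "bth", window_s = 30)
#' range(coef(f)[, "sdg"], na.rm = TRUE)  # ~0.3
#' @export
bhi_fit <- function(response, driver, t_s = NULL,
                    direction = c("bth", "htb"),
                    window_s = 15, step_s = 1, lag_s = NULL,
                    cond_max = 1e8) {
  direction <- match.arg(direction)
  n <- length(response)
  stopifnot(length(driver) == n, n >= 3L)
  if (is.null(t_s)) t_s <- seq_len(n) - 1
  dt <- t_s[2] - t_s[1]
  if (max(abs(diff(t_s) - dt)) > 1e-9 * dt) stopf("time grid must be uniform")
  lag <- max(1L, round((lag_s %||% dt) / dt))
  L <- round(window_s / dt)
  if (L < 10L) stopf("window_s must span at least 10 grid points")
  s <- max(1L, round(step_s / dt))

  # lag-aligned samples: k = (lag+1)..n
  y <- response[(lag + 1L):n]
  x2 <- driver[1L:(n - lag)]
  x1 <- if (direction == "bth") rep(1, n - lag) else response[1L:(n - lag)]
  m <- length(y)
  if (m < L) stopf("series shorter than one window")
  starts <- seq(1L, m - L + 1L, by = s)

  rs <- function(v) {
    cs <- c(0, cumsum(v))
    cs[starts + L] - cs[starts]
  }
  S11 <- rs(x1 * x1); S12 <- rs(x1 * x2); S22 <- rs(x2 * x2)
  S1y <- rs(x1 * y); S2y <- rs(x2 * y); Syy <- rs(y * y)
  det <- S11 * S22 - S12^2
  # conditioning judged on the column-normalised design (scale-free):
  # cos2 -> 1 means collinear regressors (e.g. constant driver vs intercept)
  cos2 <- ifelse(S11 > 0 & S22 > 0, pmin(S12^2 / (S11 * S22), 1), 1)
  cabs <- sqrt(cos2)
  cond <- ifelse(cabs < 1, (1 + cabs) / (1 - cabs), Inf)
  degenerate <- det <= 0 | cond > cond_max | (1 - cos2) < 1e-10
  b1 <- (S22 * S1y - S12 * S2y) / det
  b2 <- (S11 * S2y - S12 * S1y) / det
  b1[degenerate] <- NA_real_
  # eta is still estimable when only the driver is degenerate (e.g. P == 0):
  sdg_only_bad <- degenerate & (S22 - S12^2 / pmax(S11, .Machine$double.eps)) <=
    .Machine$double.eps * pmax(S22, 1)
  b1[sdg_only_bad] <- (S1y / S11)[sdg_only_bad]
  b2[degenerate] <- NA_real_
  rss <- pmax(Syy - ifelse(is.na(b1), 0, b1) * S1y -
                ifelse(is.na(b2), 0, b2) * S2y, 0)
  resid_var <- rss / pmax(L - 2, 1)
  centers <- t_s[lag + starts] + (L - 1L) * dt / 2

  cf <- cbind(b1, b2)
  colnames(cf) <- c(if (direction == "bth") "c0" else "eta", "sdg")
  structure(list(t_s = centers, coefficients = cf,
                 quality = data.frame(resid_var = resid_var, cond = cond,
                                      degenerate = degenerate),
                 direction = direction, window_s = L * dt, step_s = s * dt,
                 lag_s = lag * dt, dt = dt, n_obs = n,
                 response = response, driver = driver, grid_t = t_s,
                 call = match.call()),
            class = "bhi_fit")
}

#' Expected number of coefficient windows
#'
#' The alignment contract shared by every coupling series of one analysis
#' window: with `n` grid points of step `dt`, lag `lag` points, window `L`
#' points and step `s` points, the series has
#' `floor((n - lag - L) / s) + 1` coefficients.
#' @keywords internal
#' @export
n_bhi_windows <- function(n, window_s, step_s = 1, lag_s = 1, dt = 1) {
  L <- round(window_s / dt); s <- max(1L, round(step_s / dt))
  lag <- max(1L, round(lag_s / dt))
  as.integer(floor((n - lag - L) / s) + 1L)
}

#' @export
print.bhi_fit <- function(x, ...) {
  lab <- if (x$direction == "bth") "brain-to-heart" else "heart-to-brain"
  cat(sprintf("<bhi_fit> %s coupling, %d windows of %.3g s (step %.3g s, lag %.3g s)\n",
              lab, nrow(x$coefficients), x$window_s, x$step_s, x$lag_s))
  ok <- !x$quality$degenerate
  cat(sprintf("  median SDG %.4g (%d/%d windows valid)\n",
              stats::median(x$coefficients[ok, "sdg"]), sum(ok), length(ok)))
  invisible(x)
}

#' @export
coef.bhi_fit <- function(object, ...) object$coefficients

#' @export
summary.bhi_fit <- function(object, ...) {
  ok <- !object$quality$degenerate
  out <- list(direction = object$direction,
              n_windows = nrow(object$coefficients),
              n_valid = sum(ok),
              sdg_median = stats::median(object$coefficients[ok, "sdg"]),
              sdg_iqr = stats::IQR(object$coefficients[ok, "sdg"]),
              other_median = stats::median(object$coefficients[ok, 1L]),
              resid_var_median = stats::median(object$quality$resid_var[ok]),
              window_s = object$window_s, step_s = object$step_s,
              lag_s = object$lag_s)
  class(out) <- "summary.bhi_fit"
  out
}

#' @export
print.summary.bhi_fit <- function(x, ...) {
  lab <- if (x$direction == "bth") "brain-to-heart" else "heart-to-brain"
  cat(sprintf("Sliding-window %s coupling fit\n", lab))
  cat(sprintf("  windows: %d (%d valid), length %.3g s, step %.3g s, lag %.3g s\n",
              x$n_windows, x$n_valid, x$window_s, x$step_s, x$lag_s))
  cat(sprintf("  SDG coefficient: median %.4g, IQR %.4g\n", x$sdg_median, x$sdg_iqr))
  cat(sprintf("  %s: median %.4g; median residual variance %.4g\n",
              if (lab == "brain-to-heart") "intercept C_i0" else "AR gain eta",
              x$other_median, x$resid_var_median))
  invisible(x)
}

# time-varying one-step-ahead prediction using the coefficient series
# (each lagged sample predicted with the nearest window's coefficients)
#' @export
fitted.bhi_fit <- function(object, ...) {
  n <- object$n_obs
  lag <- round(object$lag_s / object$dt)
  ks <- (lag + 1L):n
  tk <- object$grid_t[ks]
  wi <- pmin(pmax(findInterval(tk, object$t_s), 1L), nrow(object$coefficients))
  b1 <- object$coefficients[wi, 1L]
  b2 <- object$coefficients[wi, 2L]
  x2 <- object$driver[ks - lag]
  x1 <- if (object$direction == "bth") 1 else object$response[ks - lag]
  stats::setNames(b1 * x1 + b2 * x2, NULL)
}

#' @export
residuals.bhi_fit <- function(object, ...) {
  lag <- round(object$lag_s / object$dt)
  object$response[(lag + 1L):object$n_obs] - fitted(object)
}

#' @export
predict.bhi_fit <- function(object, driver = NULL, response_lag = NULL, ...) {
  if (is.null(driver)) return(fitted(object))
  b <- apply(object$coefficients, 2, stats::median, na.rm = TRUE)
  x1 <- if (object$direction == "bth") 1 else response_lag
  b[1L] * x1 + b[2L] * driver
}

#' Forward-simulate a response series from a fitted coupling model
#'
#' Runs the fitted difference equation forward along the original driver
#' series using the time-varying coefficient estimates, adding Gaussian
#' innovations with the window-local residual variance. The parametric
#' bootstrap companion of the estimator.
#'
#' @param object a `bhi_fit`.
#' @param nsim number of simulated series.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return matrix `n_obs x nsim`.
#' @export
simulate.bhi_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_obs
  lag <- round(object$lag_s / object$dt)
  wi <- pmin(pmax(findInterval(object$grid_t, object$t_s), 1L),
             nrow(object$coefficients))
  b1 <- object$coefficients[wi, 1L]; b1[is.na(b1)] <- 0
  b2 <- object$coefficients[wi, 2L]; b2[is.na(b2)] <- 0
  sdv <- sqrt(pmax(object$quality$resid_var[wi], 0))
  out <- matrix(NA_real_, n, nsim)
  for (j in seq_len(nsim)) {
    y <- numeric(n)
    y[seq_len(lag)] <- object$response[seq_len(lag)]
    eps <- stats::rnorm(n, 0, sdv)
    for (k in (lag + 1L):n) {
      x1 <- if (object$direction == "bth") 1 else y[k - lag]
      y[k] <- b1[k] * x1 + b2[k] * object$driver[k - lag] + eps[k]
    }
    out[, j] <- y
  }
  out
}

#' @export
plot.bhi_fit <- function(x, which = c("sdg", "both"), ...) {
  which <- match.arg(which)
  ok <- !x$quality$degenerate
  lab <- if (x$direction == "bth") "SDG brain-to-heart" else "SDG heart-to-brain"
  if (which == "both") graphics::par(mfrow = c(2, 1))
  graphics::plot(x$t_s[ok], x$coefficients[ok, "sdg"], type = "l",
                 xlab = "time (s)", ylab = lab, ...)
  if (which == "both") {
    graphics::plot(x$t_s[ok], x$coefficients[ok, 1L], type = "l",
                   xlab = "time (s)", ylab = colnames(x$coefficients)[1L], ...)
  }
  invisible(x)
}

#' Brain-to-heart coupling series (wrapper)
#'
#' Regresses the HRV-band modulation amplitude on lagged EEG band power.
#'
#' @param c_i `band_power_series` of an HRV band (its `amplitude` is the
#'   response) or a numeric amplitude vector.
#' @param p_brain `band_power_series` of an EEG band (its `power` is the
#'   driver) or a numeric vector.
#' @param ... passed to [bhi_fit()].
#' @return a `bhi_fit` (direction `"bth"`).
#' @export
estimate_bth <- function(c_i, p_brain, ...) {
  resp <- if (inherits(c_i, "band_power_series")) c_i$amplitude else c_i
  drv <- if (inherits(p_brain, "band_power_series")) p_brain$power else p_brain
  t_s <- if (inherits(c_i, "band_power_series")) c_i$t_s else NULL
  if (inherits(c_i, "band_power_series") && inherits(p_brain, "band_power_series")) {
    if (length(c_i$t_s) != length(p_brain$t_s) ||
        max(abs(c_i$t_s - p_brain$t_s)) > 1e-9)
      stopf("EEG and HRV series are not on the same time grid")
  }
  bhi_fit(resp, drv, t_s = t_s, direction = "bth", ...)
}

#' Heart-to-brain coupling series (wrapper)
#'
#' Exogenous autoregression of the EEG band amplitude on its own past and
#' lagged HRV band power.
#'
#' @param a_j `band_power_series` of an EEG band (its `amplitude` is the
#'   response) or a numeric vector.
#' @param p_i `band_power_series` of an HRV band (its `power` is the driver)
#'   or a numeric vector.
#' @param ... passed to [bhi_fit()].
#' @return a `bhi_fit` (direction `"htb"`); column `eta` holds the AR gain.
#' @export
estimate_htb <- function(a_j, p_i, ...) {
  resp <- if (inherits(a_j, "band_power_series")) a_j$amplitude else a_j
  drv <- if (inherits(p_i, "band_power_series")) p_i$power else p_i
  t_s <- if (inherits(a_j, "band_power_series")) a_j$t_s else NULL
  if (inherits(a_j, "band_power_series") && inherits(p_i, "band_power_series")) {
    if (length(a_j$t_s) != length(p_i$t_s) ||
        max(abs(a_j$t_s - p_i$t_s)) > 1e-9)
      stopf("EEG and HRV series are not on the same time grid")
  }
  bhi_fit(resp, drv, t_s = t_s, direction = "htb", ...)
}
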