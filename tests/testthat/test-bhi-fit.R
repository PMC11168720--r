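# the sliding-window coupling estimator and its methods

gen_bth <- function(n, c0, sdg, p, noise = 0) {
  y <- numeric(n); y[1] <- c0
  eps <- rnorm(n, 0, noise)
  for (k in 2:n) y[k] <- c0 + sdg * p[k - 1] + eps[k]
  y
}
gen_htb <- function(n, eta, sdg, p, noise = 0, a0 = 5) {
  a <- numeric(n); a[1] <- a0
  eps <- rnorm(n, 0, noise)
  for (k in 2:n) a[k] <- eta * a[k - 1] + sdg * p[k - 1] + eps[k]
  a
}

test_that("noiseless coupling coefficients are recovered exactly", {
  set.seed(41)
  n <- 240
  p <- 1 + runif(n)
  f <- bhi_fit(gen_bth(n, 2, 0.3, p), p, direction = "bth", window_s = 15)
  expect_lt(max(abs(coef(f)[, "sdg"] - 0.3) / 0.3), 1e-9)
  expect_lt(max(abs(coef(f)[, "c0"] - 2) / 2), 1e-9)

  fh <- bhi_fit(gen_htb(n, 0.9, 0.5, p), p, direction = "htb", window_s = 15)
  expect_lt(max(abs(coef(fh)[, "sdg"] - 0.5) / 0.5), 1e-9)
  expect_lt(max(abs(coef(fh)[, "eta"] - 0.9) / 0.9), 1e-9)
  expect_false(any(fh$quality$degenerate))
})

test_that("coefficient series length obeys the shared alignment contract", {
  set.seed(42)
  p <- 1 + runif(500)
  for (W in c(15, 30, 60)) for (s in c(1, 5)) {
    f <- bhi_fit(gen_bth(500, 1, 0.2, p), p, direction = "bth",
                 window_s = W, step_s = s)
    expect_equal(nrow(coef(f)), n_bhi_windows(500, W, s))
  }
  expect_error(bhi_fit(1:20, 1:20, direction = "bth", window_s = 5),
               "at least 10 grid points")
})

test_that("scaling the driver by c scales the coupling estimate by 1/c", {
  set.seed(43)
  n <- 200
  p <- 1 + runif(n)
  y <- gen_bth(n, 2, 0.3, p)
  f1 <- bhi_fit(y, p, direction = "bth")
  f2 <- bhi_fit(y, 10 * p, direction = "bth")
  expect_equal(coef(f2)[, "sdg"] * 10, coef(f1)[, "sdg"], tolerance = 1e-9)
})

test_that("degenerate designs are flagged, not fabricated", {
  n <- 100
  y <- 2 + rnorm(n, 0, 0.1)
  f <- bhi_fit(y, rep(1, n), direction = "bth")
  expect_true(all(f$quality$degenerate))
  expect_true(all(is.na(coef(f)[, "sdg"])))
  expect_equal(unname(coef(f)[1, "c0"]), mean(y[2:16]), tolerance = 1e-9)

  # no cardiac drive: coupling unidentifiable but the AR gain is not
  set.seed(44)
  a <- gen_htb(n, 0.8, 0, rep(0, n), noise = 0.3)
  fh <- bhi_fit(a, rep(0, n), direction = "htb")
  expect_true(all(is.na(coef(fh)[, "sdg"])))
  expect_true(all(is.finite(coef(fh)[, "eta"])))
})

test_that("noisy estimates concentrate around the truth (Monte Carlo)", {
  set.seed(45)
  n <- 120
  errs <- replicate(100, {
    p <- 1 + runif(n)
    y <- gen_bth(n, 2, 0.3, p, noise = 0.1 * stats::sd(0.3 * p))
    f <- bhi_fit(y, p, direction = "bth", window_s = 60)
    median(coef(f)[, "sdg"]) - 0.3
  })
  # unbiased and within OLS sampling error
  expect_lt(abs(mean(errs)), 3 * stats::sd(errs) / sqrt(100))
  expect_lt(stats::sd(errs), 0.05)
})

test_that("a slowly ramping coupling is tracked by the window series", {
  set.seed(46)
  n <- 600
  p <- 1 + runif(n)
  sdg_t <- seq(0.2, 0.8, length.out = n)
  a <- numeric(n); a[1] <- 2
  for (k in 2:n) a[k] <- 0.7 * a[k - 1] + sdg_t[k] * p[k - 1]
  f <- bhi_fit(a, p, direction = "htb", window_s = 60)
  truth <- stats::approx(seq_len(n) - 1, sdg_t, xout = f$t_s)$y
  expect_gte(stats::cor(coef(f)[, "sdg"], truth), 0.9)
})

test_that("fitted/residuals/simulate are coherent with the model equation", {
  set.seed(47)
  n <- 150
  p <- 1 + runif(n)
  y <- gen_bth(n, 2, 0.3, p, noise = 0.05)
  f <- bhi_fit(y, p, direction = "bth", window_s = 30)
  expect_length(fitted(f), n - 1)
  expect_equal(residuals(f), y[-1] - fitted(f))
  expect_lt(stats::sd(residuals(f)), 0.08)
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(n, 3))
  expect_false(identical(sims[, 1], sims[, 2]))
  expect_identical(simulate(f, nsim = 2, seed = 9), simulate(f, nsim = 2, seed = 9))
  # summary prints the direction and the median coupling
  expect_output(print(summary(f)), "brain-to-heart")
  expect_output(print(f), "windows")
})

test_that("estimate_bth/estimate_htb enforce the common-grid contract", {
  tt <- seq(0, 300, by = 0.25)
  x <- 0.9 + 0.02 * sin(2 * pi * 0.25 * tt)
  hf <- hrv_band_power(x, "HF")
  fs <- 128
  te <- seq(0, 290, by = 1 / fs)[-1]
  th <- eeg_band_power(10 * sin(2 * pi * 6 * te), fs, "theta")
  expect_error(estimate_bth(hf, th), "grid")
})
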