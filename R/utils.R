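# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal of a real vector; its modulus is the
#' instantaneous envelope used for EEG band-amplitude estimation.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(complex(real = x, imaginary = rep(0, n)))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# centred moving average, edge-truncated (partial windows renormalised)
moving_average <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width == 1L) return(x)
  n <- length(x)
  half_lo <- (width - 1L) %/% 2L
  half_hi <- width %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# linear-convolution FIR filtering via FFT, keeping the centre (zero-phase for
# a symmetric kernel of odd length)
fft_conv_centered <- function(x, h) {
  n <- length(x); m <- length(h)
  stopifnot(m %% 2L == 1L)
  nfft <- stats::nextn(n + m - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                     stats::fft(c(h, numeric(nfft - m))), inverse = TRUE)) / nfft
  delay <- (m - 1L) %/% 2L
  y[(delay + 1L):(delay + n)]
}
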