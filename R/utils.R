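#' Analytic signal via the frequency domain
#'
#' Computes the analytic signal `x + i * H(x)` (H the Hilbert transform) by
#' zeroing negative frequencies, so that `Arg()` of the result gives the
#' instantaneous phase and `Mod()` the envelope.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(as.complex(x))
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' 1/f-shaped Gaussian noise
#'
#' White Gaussian noise spectrally shaped to a power-law (amplitude
#' proportional to 1/sqrt(f), flat below 1 Hz to keep the spectrum bounded;
#' sub-1 Hz content is removed by the high-pass filter anyway), then rescaled
#' to the requested standard deviation. Mimics the broadband background of
#' scalp EEG.
#'
#' @param n number of samples.
#' @param fs sampling rate (Hz).
#' @param sd target standard deviation (uV).
#' @return numeric vector, consumes `n` normal deviates from the RNG stream.
#' @keywords internal
pink_noise <- function(n, fs, sd = 1) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  f <- seq_len(n) - 1L
  f <- pmin(f, n - f) * fs / n       # two-sided |frequency| grid
  g <- 1 / sqrt(pmax(f, 1))
  x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE)) / n
  # scale by the theoretical SD of the shaped noise (Parseval), not the
  # realized one: an empirical rescale would pin each recording's total
  # noise power and couple its segments
  x * (sd / sqrt(mean(g^2)))
}

#' Remove per-channel linear trends
#'
#' Least-squares straight-line fit subtracted from every row.
#'
#' @param x channels x samples matrix.
#' @return matrix of the same shape with zero mean and zero linear trend rows.
#' @keywords internal
detrend_linear <- function(x) {
  n <- ncol(x)
  tc <- seq_len(n) - (n + 1) / 2
  xc <- x - rowMeans(x)
  beta <- as.numeric(xc %*% tc) / sum(tc^2)
  xc - outer(beta, tc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply an IIR filter (direct form, a[1]-normalized)
#' @keywords internal
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(numeric(nb - 1L), x), b, sides = 1)
  v <- as.numeric(v[nb:length(v)])
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  v
}

#' Zero-phase (forward-backward) IIR filtering
#'
#' Same end-padding semantics as the usual two-pass filtfilt: the signal is
#' extended with zeros by twice the filter order before the forward pass,
#' filtered again in reverse, and truncated to the original length.
#' @keywords internal
zero_phase_filter <- function(b, a, x) {
  np <- 2L * max(length(a), length(b))
  y <- iir_filter(b, a, c(x, numeric(np)))
  y <- rev(iir_filter(b, a, rev(y)))
  y[seq_along(x)]
}

#' @keywords internal
stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
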