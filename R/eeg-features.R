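# Scalar EEG features: band RMS, Hurst exponent, Petrosian and Higuchi
# fractal dimensions, and the zero-phase band filters they rely on.

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`), i.e.
#' zero phase distortion and squared magnitude response.
#'
#' @param x numeric signal.
#' @param rate sampling rate, Hz.
#' @param lo,hi band edges, Hz.
#' @param order filter order (of the prototype; band-pass doubles it).
#' @return filtered signal of the same length.
#' @export
band_filter <- function(x, rate, lo, hi, order = 4) {
  stopifnot(lo > 0, hi > lo, hi < rate / 2)
  bf <- signal::butter(order, c(lo, hi) / (rate / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# Wide-band conditioning filter: cascaded zero-phase high-pass (0.1 Hz) and
# low-pass (60 Hz) Butterworth stages. The cascade is numerically safer than
# a single band-pass with edges this close to DC and Nyquist.
broadband_filter <- function(x, rate, lo = 0.1, hi = 60) {
  hp <- signal::butter(2, lo / (rate / 2), type = "high")
  x <- signal::filtfilt(hp, x)
  if (hi < rate / 2) {
    lp <- signal::butter(4, hi / (rate / 2), type = "low")
    x <- signal::filtfilt(lp, x)
  }
  x
}

# Analysis bands (Hz). The beta upper edge of 31 Hz bounds the highest
# analysis frequency well below Nyquist at 128 Hz sampling.
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 7), alpha = c(8, 15), beta = c(16, 31))
}

#' Band RMS of a signal
#'
#' Root mean square of the band-pass filtered signal; for a pure in-band
#' sinusoid of amplitude A this equals A / sqrt(2).
#'
#' @inheritParams band_filter
#' @export
band_rms <- function(x, rate, lo, hi) {
  sqrt(mean(band_filter(x, rate, lo, hi)^2))
}

#' Hurst exponent (rescaled-range estimator)
#'
#' Prefix rescaled-range estimator: for each prefix length t the range of
#' the mean-adjusted cumulative sum is divided by the prefix SD, and the
#' Hurst exponent is the slope of log(R/S) on log(t). White noise gives
#' values near 0.5; persistent signals approach 1. Short windows (about one
#' second at 128 Hz) make this a noisy estimator; it is used as a relative
#' feature, not an absolute physical estimate.
#'
#' @param x numeric signal (length >= 8).
#' @return scalar Hurst exponent.
#' @export
hurst_exponent <- function(x) {
  n <- length(x)
  stopifnot(n >= 8)
  tt <- seq_len(n)
  y <- cumsum(x)
  ave_t <- y / tt
  # prefix SD and range of the mean-adjusted cumulative sum
  s2 <- (cumsum(x^2) - tt * ave_t^2) / tt
  s_t <- sqrt(pmax(s2, 0))
  r_t <- numeric(n)
  for (i in 2:n) {
    dev <- y[seq_len(i)] - tt[seq_len(i)] * ave_t[i]
    r_t[i] <- max(dev) - min(dev)
  }
  keep <- which(s_t > 0 & r_t > 0)
  keep <- keep[keep > 1]
  if (length(keep) < 2) return(0.5)
  fit <- stats::lsfit(log(tt[keep]), log(r_t[keep] / s_t[keep]))
  unname(fit$coefficients[2])
}

#' Petrosian fractal dimension
#'
#' `log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))` where nd counts the
#' sign changes of the first difference.
#'
#' @param x numeric signal.
#' @return scalar fractal dimension (1 for smooth, larger for noisier
#'   signals).
#' @export
petrosian_fd <- function(x) {
  n <- length(x)
  d <- diff(x)
  s <- sign(d)
  s <- s[s != 0]
  nd <- sum(diff(s) != 0)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

#' Higuchi fractal dimension
#'
#' Higuchi's curve-length method: mean normalized curve length L(k) over lag
#' k = 1..kmax; the fractal dimension is the slope of log L(k) on
#' log(1/k). White noise approaches 2, smooth signals approach 1.
#'
#' @param x numeric signal.
#' @param kmax maximum lag (default 8).
#' @return scalar fractal dimension in \[1, 2\].
#' @export
higuchi_fd <- function(x, kmax = 8) {
  n <- length(x)
  stopifnot(n > kmax + 1)
  lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    lm <- numeric(k)
    for (m in seq_len(k)) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) { lm[m] <- NA; next }
      lm[m] <- sum(abs(diff(x[idx]))) * (n - 1) /
        (k * (length(idx) - 1)) / k
    }
    lk[k] <- mean(lm, na.rm = TRUE)
  }
  ok <- lk > 0
  if (sum(ok) < 2) return(1)
  fit <- stats::lsfit(log(1 / seq_len(kmax)[ok]), log(lk[ok]))
  unname(fit$coefficients[2])
}

# The six scalar features extracted per channel and event window.
eeg_scalar_features <- function(seg, rate, theta, alpha, beta) {
  c(
    theta_rms = sqrt(mean(theta^2)),
    alpha_rms = sqrt(mean(alpha^2)),
    beta_rms = sqrt(mean(beta^2)),
    hurst = hurst_exponent(seg),
    petrosian_fd = petrosian_fd(seg),
    higuchi_fd = higuchi_fd(seg)
  )
}
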