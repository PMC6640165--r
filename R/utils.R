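# Internal numeric helpers shared across modules.

#' Clamp values to a closed interval
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Running maximum over a sliding window (stride 1)
#'
#' Returns a vector of length `length(x) - w + 1`, entry i being
#' `max(x[i:(i + w - 1)])`. Implemented with vectorised pmax over the w
#' lagged copies, which is fast for the window lengths used here (tens of
#' samples).
#' @noRd
run_max <- function(x, w) {
  n <- length(x)
  if (w > n) stop("window longer than signal")
  out <- x[seq_len(n - w + 1L)]
  if (w > 1L) {
    for (k in seq_len(w - 1L)) {
      out <- pmax(out, x[(1L + k):(n - w + 1L + k)])
    }
  }
  out
}

#' @noRd
run_min <- function(x, w) -run_max(-x, w)

#' Dilate a window-level logical vector back to sample resolution
#'
#' `fired[i]` refers to the window starting at sample i (length w); a sample
#' is marked when any window covering it fired.
#' @noRd
dilate_windows <- function(fired, w, n) {
  marked <- logical(n)
  if (!any(fired)) return(marked)
  idx <- which(fired)
  for (i in idx) marked[i:(i + w - 1L)] <- TRUE
  marked
}

#' Analytic-signal envelope via FFT
#'
#' Magnitude of the analytic signal (Hilbert transform based); for a pure
#' sinusoid of amplitude A the envelope equals A away from the edges.
#'
#' @param x numeric signal.
#' @return numeric vector of `length(x)` with the instantaneous amplitude.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1 / 128)
#' env <- hilbert_envelope(10 * sin(2 * pi * 10 * t))
#' range(env[20:230]) # close to 10
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

#' 1/f^a coloured noise
#'
#' Spectral synthesis: white Gaussian noise shaped in the frequency domain by
#' f^(-exponent/2), rescaled to the requested RMS.
#' @noRd
one_over_f_noise <- function(n, exponent = 1, rms = 1, rate = 128) {
  white <- rnorm(n)
  X <- fft(white)
  f <- seq(0, rate, length.out = n + 1)[seq_len(n)]
  # two-sided frequency axis: mirror above Nyquist
  f <- pmin(f, rate - f)
  scale <- c(0, f[-1]^(-exponent / 2)) # kill DC
  x <- Re(fft(X * scale, inverse = TRUE) / n)
  x <- x - mean(x)
  x * (rms / sqrt(mean(x^2)))
}

#' Stratified split of indices by class label
#' @noRd
stratified_split <- function(y, fraction) {
  test <- integer(0)
  for (lev in unique(y)) {
    idx <- which(y == lev)
    k <- max(1L, round(length(idx) * fraction))
    test <- c(test, sample(idx, k))
  }
  sort(test)
}

#' Stratified fold assignment (1..k) by class label
#' @noRd
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lev in unique(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
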