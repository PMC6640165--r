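# Autonomic feature pipeline: RR interpolation, frequency-domain HRV,
# tonic/phasic skin-conductance split, and event-locked summary features.

#' Cubic-spline interpolation of an RR series onto a uniform grid
#'
#' Natural cubic spline through the (beat time, RR interval) pairs,
#' evaluated on a uniform grid (default 4 Hz) spanning the observed beats;
#' no extrapolation beyond the first/last beat.
#'
#' @param beat_times beat times, s (strictly increasing, length >= 4).
#' @param rr_ms RR intervals, ms.
#' @param rate target grid rate, Hz.
#' @return data.frame with `time_s` and `rr_ms`.
#' @export
#' @examples
#' interpolate_rr(c(0, 0.8, 1.6, 2.4, 3.2), rep(800, 5))
interpolate_rr <- function(beat_times, rr_ms, rate = 4) {
  if (length(beat_times) < 4) stop("need at least 4 beats to interpolate")
  if (any(diff(beat_times) <= 0)) stop("beat times must be increasing")
  stopifnot(length(beat_times) == length(rr_ms), rate > 0)
  f <- splinefun(beat_times, rr_ms, method = "natural")
  t0 <- ceiling(beat_times[1] * rate) / rate
  t1 <- floor(beat_times[length(beat_times)] * rate) / rate
  grid <- seq(t0, t1, by = 1 / rate)
  data.frame(time_s = grid, rr_ms = f(grid))
}

#' Welch averaged-periodogram power spectral density
#'
#' Hann-windowed segments with 50% overlap, linear detrend per segment,
#' one-sided PSD normalized so that `sum(psd) * df` equals the signal's mean
#' squared amplitude (a pure sinusoid of amplitude A integrates to A^2 / 2).
#'
#' @param x numeric series (uniformly sampled).
#' @param rate sampling rate, Hz.
#' @param window_sec segment length, s; capped at the series length.
#' @param overlap fractional overlap between segments (default 0.5).
#' @param detrend remove a linear trend per segment (default TRUE).
#' @return data.frame with `freq` (Hz) and `psd` (input units squared per
#'   Hz).
#' @export
welch_psd <- function(x, rate, window_sec = 64, overlap = 0.5,
                      detrend = TRUE) {
  n <- length(x)
  stopifnot(n >= 8, rate > 0)
  nw <- min(n, round(window_sec * rate))
  hop <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = hop)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1))) # Hann
  u <- sum(w^2)
  nf <- floor(nw / 2) + 1L
  acc <- numeric(nf)
  tt <- seq_len(nw)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    if (detrend) seg <- stats::lm.fit(cbind(1, tt), seg)$residuals
    spec <- Mod(fft(seg * w))^2
    acc <- acc + spec[seq_len(nf)]
  }
  psd <- acc / (length(starts) * u * rate)
  # one-sided: double everything except DC (and Nyquist for even nw)
  scale2 <- rep(2, nf); scale2[1] <- 1
  if (nw %% 2 == 0) scale2[nf] <- 1
  data.frame(freq = (seq_len(nf) - 1) * rate / nw, psd = psd * scale2)
}

#' Heart-rate-variability band power
#'
#' Integral of the Welch PSD of the (detrended) uniform RR series over
#' `[lo, hi)` Hz. The conventional bands are HF = (0.15, 0.4) Hz and
#' LF = (0.04, 0.15) Hz.
#'
#' @param series uniform RR series: numeric vector or a data.frame with an
#'   `rr_ms` column (as from [interpolate_rr()]).
#' @param band `c(lo, hi)` in Hz.
#' @param rate series sampling rate, Hz (default 4).
#' @param window_sec Welch segment length, s (default 64).
#' @return band power, ms^2.
#' @export
hrv_band_power <- function(series, band, rate = 4, window_sec = 64) {
  if (is.data.frame(series)) series <- series$rr_ms
  stopifnot(length(band) == 2, band[2] > band[1], band[1] >= 0)
  if (band[2] > rate / 2 + 1e-12) {
    stop("band exceeds the Nyquist frequency (", rate / 2, " Hz)")
  }
  if (length(series) < 64) stop("series too short (need >= 64 samples)")
  p <- welch_psd(series, rate, window_sec = window_sec)
  df <- p$freq[2] - p$freq[1]
  sel <- p$freq >= band[1] & p$freq < band[2]
  sum(p$psd[sel]) * df
}

#' Tonic/phasic decomposition of raw skin conductance
#'
#' Stand-in decomposition for devices that do not supply the split: the
#' tonic component is a running median (default 8 s width) of the raw
#' conductance and the phasic component is the residual, so the two always
#' reconstruct the input exactly.
#'
#' @param conductance raw skin conductance, uS.
#' @param rate sampling rate, Hz.
#' @param width_sec running-median width, s (default 8).
#' @return list with `tonic` and `phasic` numeric vectors.
#' @export
decompose_gsr <- function(conductance, rate, width_sec = 8) {
  k <- round(width_sec * rate)
  if (k %% 2 == 0) k <- k + 1
  k <- min(k, if (length(conductance) %% 2 == 0)
    length(conductance) - 1 else length(conductance))
  tonic <- as.numeric(runmed(conductance, k, endrule = "median"))
  list(tonic = tonic, phasic = conductance - tonic)
}

# Sliding-window band-power "feature signal" for the RR series: power in
# `band` computed on windows of `window_sec` centred on a coarse grid, then
# linearly interpolated onto arbitrary query times.
hrv_power_signal <- function(rr, band, rate = 4, window_sec = 64,
                             hop_sec = 4) {
  t <- rr$time_s
  x <- rr$rr_ms
  n <- length(x)
  nw <- min(n, round(window_sec * rate))
  hop <- max(1L, round(hop_sec * rate))
  starts <- seq(1L, n - nw + 1L, by = hop)
  centers <- t[starts] + (nw / 2) / rate
  vals <- vapply(starts, function(s) {
    hrv_band_power(x[s:(s + nw - 1L)], band, rate = rate,
                   window_sec = window_sec)
  }, numeric(1))
  list(time = centers, value = vals)
}

sample_signal_at <- function(sig_time, sig_value, t) {
  if (length(sig_time) == 1) return(rep(sig_value, length(t)))
  approx(sig_time, sig_value, xout = t, rule = 2)$y
}

#' Extract event-locked autonomic features
#'
#' For each of the five autonomic feature signals -- HF HRV, LF HRV, tonic
#' GSR, phasic GSR, skin temperature -- computes the within-window mean
#' amplitude and peak-to-peak (max - min) for every stimulus-on event
#' window, then averages over the events of the task. The HRV feature
#' signals are sliding-window band powers of the uniform RR series
#' (window `hrv_window_sec`, centred), sampled at the event times; stimulus
#' windows are far shorter than the period of the LF band, so the spectral
#' window is necessarily wider than the event.
#'
#' @param streams a `wristband_streams` object (see [simulate_wristband()]),
#'   or a list with `rr` (`time_s`, `rr_ms`), `gsr_tonic`, `gsr_phasic`,
#'   `temperature` (`time_s`, `value`).
#' @param events data.frame with `onset` and `duration`, s.
#' @param task task label recorded in the output.
#' @param hrv_window_sec HRV spectral window length, s (default 64).
#' @return data.frame of class `ans_features`: one row per feature signal
#'   with `mean_amplitude` and `peak_to_peak`, averaged over events;
#'   attribute `n_events_used` and `skipped`.
#' @export
extract_event_ans_features <- function(streams, events, task = "task",
                                       hrv_window_sec = 64) {
  stopifnot(all(c("onset", "duration") %in% names(events)))
  rr_rate <- 1 / stats::median(diff(streams$rr$time_s))
  hf <- hrv_power_signal(streams$rr, c(0.15, 0.4), rate = rr_rate,
                         window_sec = hrv_window_sec)
  lf <- hrv_power_signal(streams$rr, c(0.04, 0.15), rate = rr_rate,
                         window_sec = hrv_window_sec)
  signals <- list(
    hf_hrv = hf,
    lf_hrv = lf,
    gsr_tonic = list(time = streams$gsr_tonic$time_s,
                     value = streams$gsr_tonic$value),
    gsr_phasic = list(time = streams$gsr_phasic$time_s,
                      value = streams$gsr_phasic$value),
    temperature = list(time = streams$temperature$time_s,
                       value = streams$temperature$value)
  )
  skipped <- 0L
  out <- lapply(names(signals), function(nm) {
    sig <- signals[[nm]]
    means <- numeric(0); p2ps <- numeric(0)
    for (e in seq_len(nrow(events))) {
      t0 <- events$onset[e]; t1 <- t0 + events$duration[e]
      if (nm %in% c("hf_hrv", "lf_hrv")) {
        # band power sampled at the event midpoint from the sliding signal
        tq <- seq(t0, t1, length.out = 5)
        vals <- sample_signal_at(sig$time, sig$value, tq)
      } else {
        sel <- sig$time >= t0 & sig$time < t1
        if (!any(sel)) { skipped <<- skipped + 1L; next }
        vals <- sig$value[sel]
      }
      means <- c(means, mean(vals))
      p2ps <- c(p2ps, max(vals) - min(vals))
    }
    data.frame(task = task, feature = nm,
               mean_amplitude = mean(means),
               peak_to_peak = mean(p2ps),
               n_events = length(means),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "skipped") <- skipped
  class(res) <- c("ans_features", class(res))
  res
}

#' Flatten ANS features to a named vector
#'
#' @param x an [extract_event_ans_features()] result.
#' @return named numeric vector `<feature>_mean`, `<feature>_p2p`.
#' @export
ans_feature_vector <- function(x) {
  out <- c(rbind(x$mean_amplitude, x$peak_to_peak))
  names(out) <- c(rbind(paste0(x$feature, "_mean"), paste0(x$feature, "_p2p")))
  out
}
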