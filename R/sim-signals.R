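# Raw-signal simulation: event timelines, EEG recordings, wristband streams.

#' Build an event timeline
#'
#' Events are half-open stimulus-on windows `[onset, onset + duration)` with
#' strictly increasing onsets. The default parameters reproduce the word
#' presentation design: 48 words shown for 1 s with a 2.75-3.25 s jittered
#' inter-stimulus interval, valences balanced 16/16/16.
#'
#' @param n_events number of events.
#' @param trial_type one of "emotional_memory", "situation_construal",
#'   "questionnaire" (free-form accepted).
#' @param duration stimulus-on duration, s.
#' @param isi_range uniform jitter range of the inter-stimulus interval, s.
#' @param start onset of the first event, s.
#' @param valences cycle of stimulus valences to balance over events, or
#'   `"n/a"`.
#' @param seed optional seed for the jitter/valence shuffle.
#' @return data.frame of class `event_timeline` with columns `onset`,
#'   `duration`, `trial_type`, `stimulus_valence`.
#' @export
#' @examples
#' tl <- make_event_timeline(n_events = 8, seed = 1)
#' head(tl)
make_event_timeline <- function(n_events = 48,
                                trial_type = "emotional_memory",
                                duration = 1,
                                isi_range = c(2.75, 3.25),
                                start = 5,
                                valences = c("pos", "neg", "neu"),
                                seed = NULL) {
  stopifnot(n_events >= 1, duration > 0, start >= 0,
            length(isi_range) == 2, all(isi_range > 0))
  if (!is.null(seed)) set.seed(as.integer(seed))
  isi <- runif(n_events, isi_range[1], isi_range[2])
  onsets <- start + c(0, cumsum(duration + isi[-n_events]))
  val <- rep_len(valences, n_events)
  if (length(valences) > 1) val <- sample(val)
  out <- data.frame(
    onset = onsets,
    duration = rep(duration, n_events),
    trial_type = trial_type,
    stimulus_valence = val,
    stringsAsFactors = FALSE
  )
  class(out) <- c("event_timeline", "data.frame")
  out
}

raised_cosine <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

#' Simulate a raw EEG recording
#'
#' Scalp signal per channel = 1/f^a background noise + 10 Hz alpha component
#' (posterior-dominant) + frontal eyeblink transients (Poisson arrivals,
#' raised-cosine waveform) + optional large-amplitude band-limited artifact
#' bursts at known, returned ground-truth times. The sync channel carries one
#' rectangular pulse per timeline event whose rising edge aligns with the
#' event onset to within one sample.
#'
#' @param timeline an [make_event_timeline()] data.frame (non-empty).
#' @param config a [sim_config()]; `config$eeg` holds the signal parameters.
#' @param participant integer participant index (seeds the RNG stream).
#' @param session "pre" or "post"; with `config$physio_effect$alpha_amplitude`
#'   set, the positive arm receives the standardized alpha shift at post.
#' @param condition 0 (negative arm) or 1 (positive arm).
#' @param duration recording length, s; default covers the timeline plus 5 s.
#' @return object of class `eeg_recording`: list with `data` (samples x
#'   channels matrix, uV), `sync`, `sampling_rate`, `montage` and
#'   `ground_truth` (blink times, artifact segments, sync onset samples,
#'   realized alpha amplitude).
#' @export
simulate_eeg <- function(timeline, config, participant = 1L,
                         session = "pre", condition = 0L, duration = NULL) {
  stopifnot(nrow(timeline) >= 1, inherits(config, "sim_config"))
  p <- config$eeg
  sr <- p$sampling_rate
  t_end <- max(timeline$onset + timeline$duration)
  if (is.null(duration)) duration <- t_end + 5
  if (t_end > duration) {
    stop("timeline extends beyond the requested duration (",
         round(t_end, 2), " > ", duration, " s)")
  }
  n <- round(duration * sr)
  ch <- p$montage
  nch <- length(ch)
  tt <- seq_len(n) / sr

  # participant-stable traits
  set.seed(derive_seed(config$seed, participant, "pre", stream = 3L))
  alpha_base <- max(0, p$alpha_amplitude + rnorm(1, 0, p$alpha_sd))
  phases <- runif(nch, 0, 2 * pi)

  # session-specific stream
  set.seed(derive_seed(config$seed, participant, session, stream = 4L))
  alpha_amp <- max(0, alpha_base + rnorm(1, 0, p$alpha_session_sd))
  if (!is.null(config$physio_effect$alpha_amplitude) &&
      session == "post" && condition == 1L) {
    alpha_amp <- alpha_amp +
      config$physio_effect$alpha_amplitude * p$alpha_sd
  }

  grp_gain <- function(name) {
    switch(substr(name, 1, 1), F = 0.5, C = 0.7, P = 1, O = 1.2, 1)
  }
  blink_gain <- function(name) {
    switch(substr(name, 1, 1), F = 1, C = 0.25, 0)
  }

  X <- matrix(0, n, nch, dimnames = list(NULL, ch))
  for (j in seq_len(nch)) {
    X[, j] <- one_over_f_noise(n, p$noise_exponent, p$noise_rms, sr) +
      alpha_amp * grp_gain(ch[j]) * sin(2 * pi * 10 * tt + phases[j])
  }

  # eyeblinks: common frontal transients
  n_blinks <- rpois(1, p$blink_rate * duration)
  blink_times <- sort(runif(n_blinks, 0, duration - p$blink_duration))
  wlen <- round(p$blink_duration * sr)
  wave <- p$blink_amplitude * raised_cosine(wlen)
  for (bt in blink_times) {
    i0 <- round(bt * sr) + 1L
    idx <- i0:(i0 + wlen - 1L)
    for (j in seq_len(nch)) {
      g <- blink_gain(ch[j])
      if (g > 0) X[idx, j] <- X[idx, j] + g * wave
    }
  }

  # large-amplitude artifact bursts on single channels
  n_art <- rpois(1, p$artifact_rate * duration)
  art <- data.frame(channel = character(0), start = numeric(0),
                    end = numeric(0))
  if (n_art > 0) {
    alen <- round(p$artifact_duration * sr)
    for (a in seq_len(n_art)) {
      st <- runif(1, 0, duration - p$artifact_duration)
      j <- sample.int(nch, 1)
      idx <- (round(st * sr) + 1L):(round(st * sr) + alen)
      burst <- stats::filter(rnorm(alen + 20), rep(1 / 8, 8), sides = 2)
      burst <- burst[11:(alen + 10)]
      burst[is.na(burst)] <- 0
      taper <- rep(1, alen)
      ramp <- max(2L, round(alen * 0.1))
      taper[seq_len(ramp)] <- seq(0, 1, length.out = ramp)
      taper[(alen - ramp + 1):alen] <- seq(1, 0, length.out = ramp)
      burst <- burst * taper
      burst <- burst * (p$artifact_amplitude / max(abs(burst)))
      X[idx, j] <- X[idx, j] + burst
      art <- rbind(art, data.frame(channel = ch[j], start = st,
                                   end = st + p$artifact_duration))
    }
  }

  # sync channel: one rectangular pulse per event
  sync <- numeric(n)
  onset_samples <- integer(nrow(timeline))
  for (e in seq_len(nrow(timeline))) {
    i0 <- round(timeline$onset[e] * sr) + 1L
    i1 <- min(n, round((timeline$onset[e] + timeline$duration[e]) * sr))
    sync[i0:i1] <- p$sync_amplitude
    onset_samples[e] <- i0
  }

  structure(
    list(
      data = X,
      sync = sync,
      sampling_rate = sr,
      montage = ch,
      ground_truth = list(
        blink_times = blink_times,
        artifacts = art,
        sync_onsets = onset_samples,
        alpha_amplitude = alpha_amp
      )
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording:", nrow(x$data), "samples x", ncol(x$data),
      "channels @", x$sampling_rate, "Hz\n")
  cat("  montage:", paste(x$montage, collapse = " "), "\n")
  gt <- x$ground_truth
  if (!is.null(gt)) {
    cat("  ground truth:", length(gt$blink_times), "blinks,",
        nrow(gt$artifacts), "artifact bursts,",
        length(gt$sync_onsets), "sync pulses\n")
  }
  invisible(x)
}

#' Simulate wristband autonomic streams
#'
#' RR-interval series = baseline + low-frequency (0.1 Hz) sinusoid +
#' high-frequency (0.25 Hz) sinusoid + beat-to-beat noise, with beat times
#' accumulated from the RR intervals themselves. Skin conductance is split
#' into a slowly drifting tonic component and a phasic component of
#' exponentially decaying responses at Poisson arrival times on a 20 Hz grid;
#' skin temperature is a bounded random walk. Realized modulation depths are
#' returned as ground truth.
#'
#' @inheritParams simulate_eeg
#' @return object of class `wristband_streams`: list with `beats`
#'   (time_s, rr_ms), `rr` (uniform grid from [interpolate_rr()]),
#'   `gsr_tonic`, `gsr_phasic`, `temperature` (each time_s, value) and
#'   `ground_truth` (lf_depth, hf_depth, scr_times).
#' @export
simulate_wristband <- function(timeline, config, participant = 1L,
                               session = "pre", condition = 0L,
                               duration = NULL) {
  stopifnot(nrow(timeline) >= 1, inherits(config, "sim_config"))
  p <- config$ans
  if (p$lf_depth < 0 || p$hf_depth < 0) {
    stop("modulation depths must be non-negative")
  }
  t_end <- max(timeline$onset + timeline$duration)
  if (is.null(duration)) duration <- t_end + 5

  set.seed(derive_seed(config$seed, participant, "pre", stream = 5L))
  lf <- if (p$lf_depth > 0) max(0, p$lf_depth + rnorm(1, 0, p$depth_sd)) else 0
  hf <- if (p$hf_depth > 0) max(0, p$hf_depth + rnorm(1, 0, p$depth_sd)) else 0
  phi_lf <- runif(1, 0, 2 * pi)
  phi_hf <- runif(1, 0, 2 * pi)

  set.seed(derive_seed(config$seed, participant, session, stream = 6L))
  shift_depth <- function(depth, name) {
    e <- config$physio_effect[[name]]
    if (!is.null(e) && session == "post" && condition == 1L) {
      depth <- max(0, depth + e * max(p$depth_sd, 1))
    }
    depth
  }
  lf <- shift_depth(lf, "lf_depth")
  hf <- shift_depth(hf, "hf_depth")

  # beats accumulated from the instantaneous RR profile
  rr_at <- function(t) {
    p$rr_baseline + lf * sin(2 * pi * 0.1 * t + phi_lf) +
      hf * sin(2 * pi * 0.25 * t + phi_hf)
  }
  est_beats <- ceiling(duration / (p$rr_baseline / 1000)) + 10L
  bt <- numeric(est_beats); rr <- numeric(est_beats)
  t <- 0; k <- 0L
  while (t < duration) {
    k <- k + 1L
    val <- rr_at(t) + if (p$rr_noise > 0) rnorm(1, 0, p$rr_noise) else 0
    val <- max(300, min(2000, val))
    bt[k] <- t; rr[k] <- val
    t <- t + val / 1000
  }
  beats <- data.frame(time_s = bt[seq_len(k)], rr_ms = rr[seq_len(k)])
  rr_grid <- interpolate_rr(beats$time_s, beats$rr_ms, rate = p$rr_rate)

  # skin conductance, 20 Hz grid
  ng <- round(duration * p$gsr_rate)
  tg <- seq_len(ng) / p$gsr_rate
  tonic <- p$tonic_level + 0.3 * sin(2 * pi * tg / 300 + runif(1, 0, 2 * pi)) +
    cumsum(rnorm(ng, 0, 0.001))
  n_scr <- rpois(1, p$scr_rate * duration)
  scr_times <- sort(runif(n_scr, 0, max(0.1, duration - 10)))
  phasic <- numeric(ng)
  if (n_scr > 0) {
    tau_r <- 0.75; tau_d <- 3
    for (st in scr_times) {
      rel <- tg - st
      w <- ifelse(rel > 0, exp(-rel / tau_d) - exp(-rel / tau_r), 0)
      w <- w / max(w)
      amp <- p$scr_amplitude * rlnorm(1, 0, 0.3)
      phasic <- phasic + amp * w
    }
  }

  nt <- round(duration * p$temp_rate)
  temp <- numeric(nt)
  temp[1] <- p$temp_baseline
  steps <- rnorm(nt, 0, 0.005)
  for (i in 2:nt) {
    temp[i] <- clamp(temp[i - 1] + steps[i],
                     p$temp_baseline - 1, p$temp_baseline + 1)
  }

  structure(
    list(
      beats = beats,
      rr = rr_grid,
      gsr_tonic = data.frame(time_s = tg, value = tonic),
      gsr_phasic = data.frame(time_s = tg, value = phasic),
      temperature = data.frame(time_s = seq_len(nt) / p$temp_rate,
                               value = temp),
      ground_truth = list(lf_depth = lf, hf_depth = hf,
                          scr_times = scr_times)
    ),
    class = "wristband_streams"
  )
}

#' @export
print.wristband_streams <- function(x, ...) {
  cat("Wristband streams:\n")
  cat("  beats:", nrow(x$beats), " (RR", round(mean(x$beats$rr_ms)), "ms)\n")
  cat("  RR grid:", nrow(x$rr), "samples\n")
  cat("  GSR:", nrow(x$gsr_tonic), "samples; temperature:",
      nrow(x$temperature), "samples\n")
  cat("  ground truth: LF depth", round(x$ground_truth$lf_depth, 1),
      "ms, HF depth", round(x$ground_truth$hf_depth, 1), "ms\n")
  invisible(x)
}
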