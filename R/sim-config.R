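# Simulation configuration: study conditions for the synthetic cohort.

#' Default self-report intervention effects
#'
#' Standardized pre-to-post mean changes (in pre-test SD units) for the 14
#' self-report well-being measures, separately for the negative-writing and
#' positive-writing arms. These defaults encode the study conditions the
#' generator emulates; five measures (elevation, gratitude, negative affect,
#' negative social emotions, positive affect) differ reliably between arms.
#'
#' @return data.frame with columns `measure`, `negative`, `positive` and
#'   `keying` (+1 for positively keyed measures, -1 for negative affect and
#'   negative social emotions).
#' @export
default_self_report_effects <- function() {
  data.frame(
    measure = c(
      "autonomy", "competence", "connectedness", "elevation", "gratitude",
      "meaning_presence", "meaning_search", "negative_affect",
      "negative_social_emotions", "optimism", "positive_affect",
      "self_esteem_appearance", "self_esteem_performance", "self_esteem_social"
    ),
    negative = c(
      -0.016, -0.033, -0.024, -0.022, -0.162,
      -0.025, -0.027, 0.068,
      0.240, -0.023, -0.179,
      0.011, -0.025, -0.001
    ),
    positive = c(
      0.018, 0.019, 0.021, 0.166, 0.037,
      0.003, 0.001, -0.085,
      -0.033, 0.018, 0.081,
      0.056, 0.042, 0.062
    ),
    keying = c(1, 1, 1, 1, 1, 1, 1, -1, -1, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Default inter-measure correlation matrix
#'
#' Exchangeable structure: |r| between every pair of measures, with the sign
#' given by the product of their keyings (negatively keyed measures --
#' negative affect, negative social emotions -- correlate negatively with the
#' positively keyed ones). This sign-flipped exchangeable form is positive
#' definite for any |r| < 1.
#'
#' @param r absolute pairwise correlation (default 0.3).
#' @param effects effect table supplying measure names and keyings.
#' @return symmetric correlation matrix with unit diagonal and dimnames.
#' @export
default_measure_correlation <- function(r = 0.3,
                                        effects = default_self_report_effects()) {
  k <- effects$keying
  R <- r * outer(k, k)
  diag(R) <- 1
  dimnames(R) <- list(effects$measure, effects$measure)
  R
}

#' EEG simulation parameters
#'
#' @param sampling_rate Hz; the target device records at 128 Hz.
#' @param montage scalp channel names (12 channels grouped into frontal,
#'   central, parietal, occipital sets downstream).
#' @param alpha_amplitude mean 10 Hz alpha amplitude, uV.
#' @param alpha_sd between-participant SD of alpha amplitude, uV.
#' @param alpha_session_sd session-to-session SD of alpha amplitude, uV.
#' @param noise_exponent spectral exponent of the 1/f^a background.
#' @param noise_rms RMS of the background noise, uV.
#' @param blink_rate eyeblink Poisson rate, Hz.
#' @param blink_amplitude blink peak amplitude, uV (raised cosine, frontal).
#' @param blink_duration blink duration, s.
#' @param artifact_rate large-amplitude artifact Poisson rate, Hz.
#' @param artifact_amplitude artifact peak amplitude, uV.
#' @param artifact_duration artifact duration, s.
#' @param sync_amplitude sync-pulse amplitude (arbitrary units).
#' @return list of class `eeg_params`.
#' @export
eeg_params <- function(sampling_rate = 128,
                       montage = c("F7", "F8", "Fz", "C3", "Cz", "C4",
                                   "P3", "P4", "P7", "P8", "Pz", "Oz"),
                       alpha_amplitude = 10,
                       alpha_sd = 2,
                       alpha_session_sd = 1,
                       noise_exponent = 1,
                       noise_rms = 8,
                       blink_rate = 0.2,
                       blink_amplitude = 100,
                       blink_duration = 0.4,
                       artifact_rate = 0.02,
                       artifact_amplitude = 600,
                       artifact_duration = 1,
                       sync_amplitude = 1000) {
  stopifnot(sampling_rate > 0, length(montage) >= 4)
  structure(as.list(environment()), class = "eeg_params")
}

#' Wristband (autonomic) simulation parameters
#'
#' @param rr_baseline mean RR interval, ms.
#' @param lf_depth low-frequency (0.1 Hz) RR modulation depth, ms.
#' @param hf_depth high-frequency (0.25 Hz, respiratory) RR modulation depth, ms.
#' @param depth_sd between-participant SD of the modulation depths, ms.
#' @param rr_noise beat-to-beat RR noise SD, ms.
#' @param rr_rate uniform grid rate for the interpolated RR series, Hz.
#' @param gsr_rate skin-conductance sample rate, Hz.
#' @param scr_rate skin-conductance-response Poisson rate, Hz.
#' @param scr_amplitude mean SCR amplitude, uS.
#' @param tonic_level tonic skin-conductance baseline, uS.
#' @param temp_baseline skin temperature baseline, degrees C.
#' @param temp_rate temperature sample rate, Hz.
#' @return list of class `ans_params`.
#' @export
ans_params <- function(rr_baseline = 800,
                       lf_depth = 20,
                       hf_depth = 20,
                       depth_sd = 5,
                       rr_noise = 5,
                       rr_rate = 4,
                       gsr_rate = 20,
                       scr_rate = 0.05,
                       scr_amplitude = 0.3,
                       tonic_level = 2,
                       temp_baseline = 33,
                       temp_rate = 4) {
  if (lf_depth < 0 || hf_depth < 0) {
    stop("modulation depths must be non-negative")
  }
  stopifnot(rr_baseline > 0, rr_rate > 0, gsr_rate > 0)
  structure(as.list(environment()), class = "ans_params")
}

#' Cognitive task simulation parameters
#'
#' @param hit_prob per-valence probability of clicking an old word.
#' @param fa_prob per-valence probability of clicking a new (distractor) word.
#' @param n_per_cell old (and new) words per valence; 16 in the source design.
#' @param construal_strength latent construal signal per image valence on the
#'   normalized (-1, 1) scale (positive images construed positively, etc.).
#' @param construal_sd latent rating noise SD (rating points).
#' @param rt_meanlog,rt_sdlog lognormal reaction-time parameters (seconds).
#' @param find_gap_mean mean gap between consecutive word-find discoveries, s.
#' @return list of class `cognitive_params`.
#' @export
cognitive_params <- function(hit_prob = c(pos = 0.70, neg = 0.70, neu = 0.70),
                             fa_prob = c(pos = 0.20, neg = 0.20, neu = 0.20),
                             n_per_cell = 16,
                             construal_strength = c(pos = 0.6, neg = -0.6,
                                                    amb = 0),
                             construal_sd = 1,
                             rt_meanlog = log(2.5),
                             rt_sdlog = 0.4,
                             find_gap_mean = 35) {
  stopifnot(all(hit_prob >= 0 & hit_prob <= 1),
            all(fa_prob >= 0 & fa_prob <= 1),
            n_per_cell >= 1, find_gap_mean > 0)
  structure(as.list(environment()), class = "cognitive_params")
}

#' Simulation configuration for a synthetic study
#'
#' Bundles every generator parameter: cohort size and randomization ratio,
#' per-arm standardized self-report effects, inter-measure correlation,
#' change-score noise, optional injected cognitive and physiological effects,
#' and the raw-signal parameter blocks.
#'
#' @param n_participants cohort size (>= 4). Default 245, the pooled sample
#'   of the two-experiment design the generator emulates.
#' @param condition_ratio fraction assigned to the positive-writing arm.
#' @param seed integer seed; every generator derives its stream from it.
#' @param self_report_effects data.frame(measure, negative, positive) of
#'   standardized pre-to-post mean changes per arm.
#' @param measure_correlation positive semi-definite correlation matrix over
#'   the self-report measures (unit diagonal).
#' @param change_sd SD of the pre-to-post change noise in pre-test SD units.
#'   Default 0.45, i.e. test-retest reliability about 0.9 over the session.
#' @param cognitive_effects optional named list of `(negative, positive)`
#'   standardized shifts applied to cognitive task parameters at post-test;
#'   names like `"d_prime_pos"`, `"construal_rn_neg"`, `"find_time_neu"`.
#'   Default NULL: no cognitive condition effects.
#' @param physio_effect optional named list of standardized shifts applied in
#'   the positive arm at post-test to physiological ground truth; supported
#'   names: `"alpha_amplitude"`, `"hf_depth"`, `"lf_depth"`.
#' @param eeg [eeg_params()] block.
#' @param ans [ans_params()] block.
#' @param cognitive [cognitive_params()] block.
#' @return list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_participants = 20, seed = 42)
#' cohort <- generate_cohort(cfg)
sim_config <- function(n_participants = 245,
                       condition_ratio = 0.5,
                       seed = 1L,
                       self_report_effects = default_self_report_effects(),
                       measure_correlation = default_measure_correlation(
                         effects = self_report_effects),
                       change_sd = 0.45,
                       cognitive_effects = NULL,
                       physio_effect = NULL,
                       eeg = eeg_params(),
                       ans = ans_params(),
                       cognitive = cognitive_params()) {
  if (n_participants < 4) stop("n_participants must be >= 4")
  if (condition_ratio <= 0 || condition_ratio >= 1) {
    stop("condition_ratio must lie strictly between 0 and 1")
  }
  seed <- as.integer(seed)
  stopifnot(is.data.frame(self_report_effects),
            all(c("measure", "negative", "positive") %in%
                  names(self_report_effects)))
  m <- nrow(self_report_effects)
  R <- measure_correlation
  if (!is.matrix(R) || nrow(R) != m || ncol(R) != m) {
    stop("measure_correlation must be a ", m, "x", m,
         " matrix matching self_report_effects")
  }
  if (max(abs(diag(R) - 1)) > 1e-8) {
    stop("measure_correlation must have a unit diagonal")
  }
  if (max(abs(R - t(R))) > 1e-8) {
    stop("measure_correlation must be symmetric")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("measure_correlation is not positive semi-definite ",
         "(smallest eigenvalue ", format(min(ev)), ")")
  }
  if (change_sd < 0) stop("change_sd must be non-negative")
  structure(
    list(
      n_participants = as.integer(n_participants),
      condition_ratio = condition_ratio,
      seed = seed,
      self_report_effects = self_report_effects,
      measure_correlation = R,
      change_sd = change_sd,
      cognitive_effects = cognitive_effects,
      physio_effect = physio_effect,
      eeg = eeg,
      ans = ans,
      cognitive = cognitive
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  participants:", x$n_participants,
      sprintf("(positive arm fraction %.2f)", x$condition_ratio), "\n")
  cat("  seed:", x$seed, "\n")
  cat("  self-report measures:", nrow(x$self_report_effects), "\n")
  cat("  change-score SD:", x$change_sd, "\n")
  cat("  cognitive effects:",
      if (is.null(x$cognitive_effects)) "none (null)" else
        paste(names(x$cognitive_effects), collapse = ", "), "\n")
  cat("  physio effects:",
      if (is.null(x$physio_effect)) "none (null)" else
        paste(names(x$physio_effect), collapse = ", "), "\n")
  invisible(x)
}

# Deterministic per-participant / per-session seed derivation. Keeps all
# derived seeds well inside 32-bit integer range for base R's RNG.
derive_seed <- function(seed, participant = 0L, session = "pre",
                        stream = 0L) {
  s <- (as.integer(seed) %% 100000L) * 13L +
    as.integer(participant) * 7919L +
    (if (identical(session, "post")) 3571L else 0L) +
    as.integer(stream) * 97L
  s %% 2147483629L
}
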