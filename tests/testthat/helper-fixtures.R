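# Shared fixture builders and independent oracles.

# Recognition log with exact hit/false-alarm counts per valence.
make_recognition_log <- function(hits, fas, n_old = 16, n_new = n_old,
                                 valence = "pos") {
  old <- data.frame(
    valence = valence, is_old = TRUE,
    clicked = c(rep(TRUE, hits), rep(FALSE, n_old - hits))
  )
  new <- data.frame(
    valence = valence, is_old = FALSE,
    clicked = c(rep(TRUE, fas), rep(FALSE, n_new - fas))
  )
  rbind(old, new)
}

# Construal log rows.
make_construal_log <- function(ratings, polarities,
                               image_valence = "pos", rt = 1) {
  data.frame(
    image_valence = image_valence,
    item_polarity = polarities,
    rating = ratings,
    reaction_time = rt
  )
}

# Word-find log from an order permutation (valences in groups of 3).
make_word_find_log <- function(order = sample(9),
                               times = sort(runif(9, 1000, 60000))) {
  data.frame(
    word_id = paste0("w", 1:9),
    valence = rep(c("pos", "neg", "neu"), each = 3),
    find_order = order,
    find_time = times[order]
  )
}

# Independent probit oracle: numeric inversion of the normal CDF.
probit_oracle <- function(p) {
  stats::uniroot(function(z) stats::pnorm(z) - p,
                 interval = c(-10, 10), tol = 1e-12)$root
}

# Synthetic EEG recording wrapper around a plain matrix.
make_recording <- function(data, sr = 128, sync = numeric(nrow(data))) {
  if (is.null(colnames(data))) {
    colnames(data) <- c("F7", "F8", "Fz", "C3", "Cz", "C4",
                        "P3", "P4", "P7", "P8", "Pz", "Oz")[seq_len(ncol(data))]
  }
  structure(
    list(data = data, sync = sync, sampling_rate = sr,
         montage = colnames(data), ground_truth = NULL),
    class = "eeg_recording"
  )
}

# 99% binomial confidence half-width around 0.5 for n predictions.
chance_ci_halfwidth <- function(n) 2.576 * sqrt(0.25 / n)
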