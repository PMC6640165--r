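# EEG preprocessing and event-locked feature extraction:
# sync-edge event detection, band-pass + average reference + blink removal,
# threshold/envelope artifact rejection, Table-of-features extraction, PCA.

#' Detect sync-pulse edges
#'
#' Localizes the sharp rising and/or falling edges of the rectangular pulses
#' on the photodiode sync channel. An edge is a first-difference exceeding
#' the threshold (default: half the largest absolute step); consecutive
#' supra-threshold samples are collapsed onto the first.
#'
#' @param sync numeric sync-channel samples.
#' @param sampling_rate Hz (unused by the detection itself; kept so callers
#'   can convert onsets to seconds).
#' @param edges which edges count as event onsets.
#' @param threshold absolute first-difference threshold; default is adaptive.
#' @return integer vector of strictly increasing onset sample indices; empty
#'   (with a warning) when no edge is present.
#' @export
detect_sync_events <- function(sync, sampling_rate = 128,
                               edges = c("rising", "falling", "both"),
                               threshold = NULL) {
  edges <- match.arg(edges)
  d <- diff(sync)
  if (is.null(threshold)) {
    mx <- max(abs(d))
    if (mx <= .Machine$double.eps^0.5) {
      warning("no sync edges found")
      return(integer(0))
    }
    threshold <- mx / 2
  }
  hit <- switch(edges,
    rising = d > threshold,
    falling = d < -threshold,
    both = abs(d) > threshold
  )
  idx <- which(hit) + 1L
  if (length(idx) == 0) {
    warning("no sync edges found")
    return(integer(0))
  }
  # collapse runs of consecutive indices onto their first sample
  idx[c(TRUE, diff(idx) > 1L)]
}

#' Preprocess an EEG recording
#'
#' Applies, in order: zero-phase band-pass conditioning (0.1-60 Hz), removal
#' of listed bad channels, re-referencing to the mean of the remaining good
#' channels, and automatic eyeblink removal. Blink removal decomposes the
#' channels spatially (SVD); a component is flagged as the blink when its
#' spatial pattern is frontal-dominant (frontal channels carry more than half
#' of the squared loading) and its time course concentrates more than 60% of
#' its power below 4 Hz. The highest-variance flagged component is subtracted
#' and the data re-referenced again. All decisions are recorded in the
#' `preprocess_log` attribute.
#'
#' @param rec an `eeg_recording` (see [simulate_eeg()]), or any list with
#'   `data` (samples x channels, named columns), `sampling_rate`, `montage`.
#' @param bad_channels channel names to drop before re-referencing.
#' @param blink_removal logical; disable to keep blinks.
#' @return cleaned `eeg_recording` with attribute `preprocess_log` (list:
#'   bad_channels, blink_component, blink_frontal_share, blink_lowfreq_share,
#'   blink_removed).
#' @export
preprocess_eeg <- function(rec, bad_channels = character(0),
                           blink_removal = TRUE) {
  X <- rec$data
  sr <- rec$sampling_rate
  keep <- setdiff(colnames(X), bad_channels)
  if (length(keep) < 4) {
    stop("fewer than 4 good channels remain after removing: ",
         paste(bad_channels, collapse = ", "))
  }
  X <- X[, keep, drop = FALSE]
  for (j in seq_len(ncol(X))) X[, j] <- broadband_filter(X[, j], sr)
  X <- X - rowMeans(X)

  log <- list(bad_channels = bad_channels, blink_component = NA_integer_,
              blink_frontal_share = NA_real_, blink_lowfreq_share = NA_real_,
              blink_removed = FALSE, decomposition_failed = FALSE)

  if (blink_removal) {
    dec <- tryCatch(svd(X), error = function(e) NULL)
    if (is.null(dec)) {
      warning("spatial decomposition failed; blink removal skipped")
      log$decomposition_failed <- TRUE
    } else {
      frontal <- grepl("^F", keep)
      n_comp <- min(ncol(X), 10L)
      flagged <- integer(0)
      shares <- matrix(NA_real_, n_comp, 2)
      for (kk in seq_len(n_comp)) {
        v <- dec$v[, kk]
        fr_share <- sum(v[frontal]^2) / sum(v^2)
        tc <- dec$u[, kk]
        spec <- Mod(fft(tc))^2
        nf <- length(spec)
        f <- seq(0, sr, length.out = nf + 1)[seq_len(nf)]
        f <- pmin(f, sr - f)
        low_share <- sum(spec[f < 4]) / sum(spec)
        shares[kk, ] <- c(fr_share, low_share)
        if (fr_share > 0.5 && low_share > 0.6) flagged <- c(flagged, kk)
      }
      if (length(flagged) > 0) {
        kk <- flagged[1] # components ordered by variance
        X <- X - dec$d[kk] * tcrossprod(dec$u[, kk], dec$v[, kk])
        X <- X - rowMeans(X)
        log$blink_component <- kk
        log$blink_frontal_share <- shares[kk, 1]
        log$blink_lowfreq_share <- shares[kk, 2]
        log$blink_removed <- TRUE
      }
    }
  }

  out <- rec
  out$data <- X
  out$montage <- keep
  attr(out, "preprocess_log") <- log
  out
}

#' Mark artifact-contaminated samples
#'
#' Per channel, a 0.3 s sliding window (stride one sample) is marked when any
#' of three rules fires: (1) absolute amplitude of the channel above
#' `abs_threshold` uV, (2) within-window peak-to-peak above `p2p_threshold`
#' uV, (3) Hilbert envelope of any band-filtered copy (delta 1-4, theta 4-7,
#' alpha 8-15, beta 16-31 Hz) above `envelope_threshold` uV. The mask is the
#' union over rules and bands, expanded back to sample resolution.
#'
#' @param rec (preprocessed) `eeg_recording`.
#' @param abs_threshold rule-1 threshold, uV (default 400).
#' @param p2p_threshold rule-2 threshold, uV (default 400).
#' @param envelope_threshold rule-3 threshold, uV (default 40).
#' @param window sliding-window length, s (default 0.3).
#' @return logical matrix (samples x channels, TRUE = contaminated) of class
#'   `artifact_mask` with the thresholds attached as attributes.
#' @export
mark_artifacts <- function(rec, abs_threshold = 400, p2p_threshold = 400,
                           envelope_threshold = 40, window = 0.3) {
  X <- rec$data
  sr <- rec$sampling_rate
  w <- max(2L, round(window * sr))
  n <- nrow(X)
  bands <- eeg_bands()
  mask <- matrix(FALSE, n, ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    fired <- run_max(abs(x), w) > abs_threshold
    fired <- fired | (run_max(x, w) - run_min(x, w)) > p2p_threshold
    for (b in bands) {
      env <- hilbert_envelope(band_filter(x, sr, b[1], b[2]))
      fired <- fired | run_max(env, w) > envelope_threshold
    }
    mask[, j] <- dilate_windows(fired, w, n)
  }
  structure(mask, class = c("artifact_mask", class(mask)),
            abs_threshold = abs_threshold, p2p_threshold = p2p_threshold,
            envelope_threshold = envelope_threshold, window = window)
}

#' Default channel groups
#'
#' Frontal, central, parietal and occipital channel groups used for feature
#' averaging.
#' @return named list of channel-name vectors.
#' @export
default_channel_groups <- function() {
  list(F = c("F7", "F8", "Fz"),
       C = c("Cz", "C3", "C4"),
       P = c("P3", "P4", "P7", "P8", "Pz"),
       O = "Oz")
}

#' Default alpha-asymmetry electrode pairs
#' @return list of (left, right) channel-name pairs.
#' @export
default_asymmetry_pairs <- function() {
  list(c("F7", "F8"), c("P3", "P4"), c("P7", "P8"))
}

#' Extract event-locked EEG features
#'
#' For every event window and channel, computes theta/alpha/beta band RMS
#' (on band-filtered copies of the whole channel, so window features are
#' shift-consistent), the Hurst exponent, and the Petrosian and Higuchi
#' fractal dimensions of the raw window. Windows with more than
#' `max_masked_fraction` contaminated samples (per channel) are dropped.
#' Features are averaged over events per channel and then over channels
#' within each group; alpha asymmetry is the difference in event-averaged
#' alpha RMS, right minus left, for each configured pair.
#'
#' @param rec preprocessed `eeg_recording`.
#' @param events data.frame with `onset` and `duration` in seconds (an
#'   [make_event_timeline()] works), or a numeric vector of onset seconds
#'   combined with `window`.
#' @param mask optional [mark_artifacts()] result.
#' @param groups named list of channel groups
#'   (default [default_channel_groups()]).
#' @param asymmetry_pairs list of (left, right) channel pairs.
#' @param window event window length in s used when `events` has no
#'   durations (default 1).
#' @param max_masked_fraction drop a channel-event when more than this
#'   fraction of its samples is masked (default 0.5).
#' @return list of class `eeg_features`: `features` (data.frame, one row per
#'   channel group with the 6 scalar features), `asymmetry` (data.frame,
#'   one row per pair), `n_events_used` (per channel), `dropped` (count).
#' @export
extract_event_features <- function(rec, events, mask = NULL,
                                   groups = default_channel_groups(),
                                   asymmetry_pairs = default_asymmetry_pairs(),
                                   window = 1,
                                   max_masked_fraction = 0.5) {
  X <- rec$data
  sr <- rec$sampling_rate
  n <- nrow(X)
  if (is.numeric(events) && is.null(dim(events))) {
    events <- data.frame(onset = events, duration = window)
  }
  stopifnot(all(c("onset", "duration") %in% names(events)))
  if (any(events$onset < 0) ||
      any(round((events$onset + events$duration) * sr) > n)) {
    stop("events fall outside the recording")
  }
  bands <- eeg_bands()
  nch <- ncol(X)
  filtered <- list(
    theta = apply(X, 2, band_filter, rate = sr,
                  lo = bands$theta[1], hi = bands$theta[2]),
    alpha = apply(X, 2, band_filter, rate = sr,
                  lo = bands$alpha[1], hi = bands$alpha[2]),
    beta = apply(X, 2, band_filter, rate = sr,
                 lo = bands$beta[1], hi = bands$beta[2])
  )

  feat_names <- c("theta_rms", "alpha_rms", "beta_rms", "hurst",
                  "petrosian_fd", "higuchi_fd")
  acc <- array(0, dim = c(nch, length(feat_names)),
               dimnames = list(colnames(X), feat_names))
  used <- integer(nch); names(used) <- colnames(X)
  dropped <- 0L
  for (e in seq_len(nrow(events))) {
    i0 <- round(events$onset[e] * sr) + 1L
    i1 <- min(n, i0 + round(events$duration[e] * sr) - 1L)
    idx <- i0:i1
    for (j in seq_len(nch)) {
      if (!is.null(mask) && mean(mask[idx, j]) > max_masked_fraction) {
        dropped <- dropped + 1L
        next
      }
      acc[j, ] <- acc[j, ] + eeg_scalar_features(
        X[idx, j], sr,
        filtered$theta[idx, j], filtered$alpha[idx, j], filtered$beta[idx, j]
      )
      used[j] <- used[j] + 1L
    }
  }
  per_channel <- acc / ifelse(used > 0, used, NA)

  rows <- lapply(names(groups), function(g) {
    chs <- intersect(groups[[g]], colnames(X))
    chs <- chs[used[chs] > 0]
    if (length(chs) == 0) return(NULL) # all windows masked for this group
    vals <- colMeans(per_channel[chs, , drop = FALSE])
    cbind(data.frame(channel_group = g, stringsAsFactors = FALSE),
          as.data.frame(as.list(vals)))
  })
  features <- do.call(rbind, rows)

  asym <- lapply(asymmetry_pairs, function(pr) {
    if (!all(pr %in% colnames(X)) || any(used[pr] == 0)) return(NULL)
    data.frame(pair = paste(pr, collapse = "-"),
               alpha_asymmetry = per_channel[pr[2], "alpha_rms"] -
                 per_channel[pr[1], "alpha_rms"],
               stringsAsFactors = FALSE)
  })
  structure(
    list(features = features,
         asymmetry = do.call(rbind, asym),
         n_events_used = used,
         dropped = dropped),
    class = "eeg_features"
  )
}

#' @export
print.eeg_features <- function(x, ...) {
  cat("Event-locked EEG features (", nrow(x$features), "channel groups x",
      ncol(x$features) - 1, "scalar features )\n")
  print(x$features, digits = 4)
  if (!is.null(x$asymmetry)) {
    cat("Alpha asymmetry (right - left):\n")
    print(x$asymmetry, digits = 4)
  }
  invisible(x)
}

#' Flatten EEG features to a named vector
#'
#' One named entry per channel group x scalar feature (24 with the default
#' four groups), followed by the alpha-asymmetry pairs.
#'
#' @param x an [extract_event_features()] result.
#' @param include_asymmetry append asymmetry entries (default TRUE).
#' @return named numeric vector.
#' @export
eeg_feature_vector <- function(x, include_asymmetry = TRUE) {
  f <- x$features
  scalars <- setdiff(names(f), "channel_group")
  out <- numeric(0)
  for (i in seq_len(nrow(f))) {
    v <- unlist(f[i, scalars])
    names(v) <- paste(f$channel_group[i], scalars, sep = "_")
    out <- c(out, v)
  }
  if (include_asymmetry && !is.null(x$asymmetry)) {
    a <- x$asymmetry$alpha_asymmetry
    names(a) <- paste0("alpha_asym_", x$asymmetry$pair)
    out <- c(out, a)
  }
  out
}

#' Principal-component reduction of a feature table
#'
#' Columns are standardized (zero mean, unit variance) before the
#' decomposition; the first k component scores and the orthonormal loading
#' matrix are returned. Near-constant columns are dropped with a warning;
#' if k exceeds the table's rank, the available components are returned with
#' a warning.
#'
#' @param x numeric matrix or data.frame (observations x variables).
#' @param k number of components (default 5).
#' @return object of class `pca_reduction`: list with `scores` (n x k),
#'   `loadings` (p x k, orthonormal columns), `explained` (variance
#'   fractions, nonincreasing), `center`, `scale`, `dropped_columns`.
#' @export
reduce_pca <- function(x, k = 5) {
  x <- as.matrix(x)
  stopifnot(nrow(x) >= 2)
  sds <- apply(x, 2, sd)
  drop <- sds < 1e-12
  dropped_cols <- colnames(x)[drop]
  if (any(drop)) {
    warning("dropping near-constant columns: ",
            paste(dropped_cols, collapse = ", "))
    x <- x[, !drop, drop = FALSE]
  }
  if (nrow(x) < k + 1) {
    warning("fewer than k + 1 rows; components limited by sample size")
  }
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-9)
  k_eff <- min(k, ncol(pc$rotation))
  if (rank < k) {
    warning("requested ", k, " components but rank is ", rank,
            "; trailing components have (near) zero variance")
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = pc$x[, seq_len(k_eff), drop = FALSE],
         loadings = pc$rotation[, seq_len(k_eff), drop = FALSE],
         explained = expl[seq_len(k_eff)],
         center = pc$center,
         scale = pc$scale,
         dropped_columns = dropped_cols),
    class = "pca_reduction"
  )
}

#' @export
print.pca_reduction <- function(x, ...) {
  cat("PCA reduction:", ncol(x$scores), "components from",
      nrow(x$loadings), "variables\n")
  cat("  explained variance fractions:",
      paste(sprintf("%.3f", x$explained), collapse = " "), "\n")
  invisible(x)
}

#' Project new data onto a fitted PCA reduction
#'
#' @param object a [reduce_pca()] fit.
#' @param newdata matrix/data.frame with the variables the fit was trained
#'   on.
#' @param ... unused.
#' @return score matrix (rows x components).
#' @export
predict.pca_reduction <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)[, names(object$center), drop = FALSE]
  scale(nd, center = object$center, scale = object$scale) %*% object$loadings
}
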