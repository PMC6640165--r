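# EEG preprocessing, artifact rejection and feature extraction.

test_that("sync edges are detected to within one sample", {
  sync <- numeric(2000)
  sync[1281:1409] <- 1000
  expect_identical(detect_sync_events(sync), 1281L)
  expect_identical(detect_sync_events(sync, edges = "falling"), 1410L)
  expect_identical(detect_sync_events(sync, edges = "both"),
                   c(1281L, 1410L))
  expect_warning(out <- detect_sync_events(numeric(100)), "no sync edges")
  expect_length(out, 0)

  # round trip against the simulator's ground truth, 48 word events
  cfg <- sim_config(n_participants = 4, seed = 8)
  tl <- make_event_timeline(n_events = 48, seed = 2)
  rec <- simulate_eeg(tl, cfg)
  onsets <- detect_sync_events(rec$sync, rec$sampling_rate)
  expect_length(onsets, 48)
  expect_lte(max(abs(onsets - rec$ground_truth$sync_onsets)), 1)
})

test_that("preprocessing re-references, removes DC and strips blinks", {
  cfg <- sim_config(n_participants = 4, seed = 3,
                    eeg = eeg_params(blink_rate = 0.5, artifact_rate = 0))
  tl <- make_event_timeline(n_events = 10, seed = 1)
  rec <- simulate_eeg(tl, cfg, duration = 50)

  pp <- preprocess_eeg(rec)
  expect_lt(max(abs(rowMeans(pp$data))), 1e-9)

  # DC offset is removed by the 0.1 Hz high-pass
  rec_dc <- rec
  rec_dc$data <- rec_dc$data + 100
  pp_dc <- preprocess_eeg(rec_dc, blink_removal = FALSE)
  expect_lt(abs(mean(pp_dc$data)), 1)

  # blink removal halves frontal low-frequency variance at least
  pp_raw <- preprocess_eeg(rec, blink_removal = FALSE)
  lowvar <- function(X) mean(band_filter(X[, "F7"], 128, 0.5, 4)^2)
  expect_true(attr(pp, "preprocess_log")$blink_removed)
  expect_lt(lowvar(pp$data), 0.5 * lowvar(pp_raw$data))

  # bad channels are dropped; fewer than 4 good channels errors
  pp_bad <- preprocess_eeg(rec, bad_channels = c("Oz", "Pz"))
  expect_false("Oz" %in% pp_bad$montage)
  expect_error(preprocess_eeg(rec, bad_channels = rec$montage[1:9]),
               "fewer than 4")
})

test_that("artifact rules fire on amplitude, peak-to-peak and envelope", {
  n <- 128 * 6
  t <- seq_len(n) / 128
  flat <- matrix(0, n, 4)
  # rule 1: constant 500 uV segment
  sig <- flat; sig[300:500, 1] <- 500
  mask <- mark_artifacts(make_recording(sig))
  expect_true(all(mask[350:450, 1]))
  expect_false(any(mask[, 2]))

  # rule 3: 10 uV alpha sine passes, 50 uV is flagged via its envelope
  sine10 <- flat; sine10[, 1] <- 10 * sin(2 * pi * 10 * t)
  expect_false(any(mark_artifacts(make_recording(sine10))[, 1]))
  sine50 <- flat; sine50[, 1] <- 50 * sin(2 * pi * 10 * t)
  m50 <- mark_artifacts(make_recording(sine50))
  expect_true(mean(m50[, 1]) > 0.9)
  # but not with a raised envelope threshold: monotonicity in thresholds
  m50_hi <- mark_artifacts(make_recording(sine50), envelope_threshold = 80)
  expect_lte(sum(m50_hi), sum(m50))
  expect_false(any(m50_hi[, 1]))

  # raising any threshold never flags more samples
  set.seed(6)
  noisy <- matrix(rnorm(n * 4, sd = 150), n, 4)
  base <- sum(mark_artifacts(make_recording(noisy)))
  expect_lte(sum(mark_artifacts(make_recording(noisy),
                                abs_threshold = 500)), base)
  expect_lte(sum(mark_artifacts(make_recording(noisy),
                                p2p_threshold = 500)), base)
  expect_lte(sum(mark_artifacts(make_recording(noisy),
                                envelope_threshold = 60)), base)

  # all-zero signal yields an all-false mask
  expect_false(any(mark_artifacts(make_recording(flat))))
})

test_that("event features recover known signal structure", {
  n <- 128 * 20
  t <- seq_len(n) / 128
  A <- 12
  X <- matrix(rep(A * sin(2 * pi * 10 * t), 12), n, 12)
  rec <- make_recording(X)
  events <- data.frame(onset = c(3, 7, 11), duration = 2)
  f <- extract_event_features(rec, events)
  expect_equal(f$features$alpha_rms, rep(A / sqrt(2), 4),
               tolerance = 1e-3)
  expect_lt(max(f$features$theta_rms), 0.05 * A)
  expect_lt(max(f$features$beta_rms), 0.05 * A)
  # identical left and right channels: zero asymmetry
  expect_equal(f$asymmetry$alpha_asymmetry, rep(0, 3))

  # white noise has Hurst exponent near one half
  set.seed(2)
  Xn <- matrix(rnorm(n * 12), n, 12)
  fn <- extract_event_features(make_recording(Xn),
                               data.frame(onset = seq(2, 16, by = 2),
                                          duration = 1))
  expect_lt(abs(mean(fn$features$hurst) - 0.5), 0.1)
  expect_true(all(fn$features$petrosian_fd > 1))
  expect_true(all(fn$features$higuchi_fd > 1.5)) # noise is rough

  # masked windows are dropped
  mask <- matrix(FALSE, n, 12, dimnames = list(NULL, colnames(Xn)))
  mask[(2 * 128):(3.5 * 128), ] <- TRUE
  fm <- extract_event_features(make_recording(Xn),
                               data.frame(onset = c(2, 8), duration = 1),
                               mask = mask)
  expect_equal(unname(fm$n_events_used["F7"]), 1L)
  expect_gt(fm$dropped, 0)

  # events outside the recording error
  expect_error(extract_event_features(rec,
                                      data.frame(onset = 25, duration = 1)),
               "outside")
})

test_that("features are stable under whole-sample event shifts", {
  set.seed(3)
  n <- 128 * 20
  X <- matrix(rnorm(n * 4), n, 4)
  rec <- make_recording(X)
  groups <- list(F = c("F7", "F8"), C = c("Fz", "C3"))
  ev <- data.frame(onset = c(4, 9, 14), duration = 1)
  f1 <- extract_event_features(rec, ev, groups = groups,
                               asymmetry_pairs = list(c("F7", "F8")))
  # sub-sample onset jitter below half a sample rounds to the same windows
  ev2 <- ev; ev2$onset <- ev$onset + 0.3 / 128
  f2 <- extract_event_features(rec, ev2, groups = groups,
                               asymmetry_pairs = list(c("F7", "F8")))
  expect_identical(f1$features, f2$features)

  # shifting signal and events together by whole samples preserves features
  k <- 256
  Xs <- rbind(matrix(0, k, 4), X[seq_len(n - k), ])
  ev3 <- ev; ev3$onset <- ev$onset + k / 128
  f3 <- extract_event_features(make_recording(Xs), ev3, groups = groups,
                               asymmetry_pairs = list(c("F7", "F8")))
  expect_equal(f1$features$alpha_rms, f3$features$alpha_rms,
               tolerance = 1e-6)
  expect_equal(f1$features$hurst, f3$features$hurst, tolerance = 1e-6)
})

test_that("PCA reduction is orthonormal, rank-aware and row-equivariant", {
  set.seed(11)
  base <- matrix(rnorm(30 * 2), 30, 2)
  x <- base %*% matrix(rnorm(2 * 8), 2, 8) # rank 2
  colnames(x) <- paste0("v", 1:8)
  expect_warning(red <- reduce_pca(x, k = 5), "rank")
  expect_lt(sum(red$explained[3:5]), 1e-9)
  ltl <- crossprod(red$loadings)
  expect_equal(ltl, diag(ncol(red$loadings)), tolerance = 1e-9,
               ignore_attr = TRUE)

  xf <- matrix(rnorm(30 * 8), 30, 8)
  colnames(xf) <- paste0("v", 1:8)
  full <- reduce_pca(xf, k = 5)
  expect_equal(length(full$explained), 5)
  expect_true(all(diff(full$explained) <= 1e-12))

  perm <- sample(30)
  red_p <- reduce_pca(xf[perm, ], k = 5)
  # same decomposition up to column sign
  for (j in 1:5) {
    s <- sign(sum(red_p$loadings[, j] * full$loadings[, j]))
    expect_equal(red_p$scores[, j], s * full$scores[perm, j],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }

  # 24-variable feature table reduces to 5 components
  x24 <- matrix(rnorm(40 * 24), 40, 24)
  colnames(x24) <- paste0("f", 1:24)
  expect_equal(ncol(reduce_pca(x24, k = 5)$scores), 5)
})
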