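# Synthetic cohort, cognitive logs, and raw-signal generators.

test_that("generate_cohort is deterministic and validates its config", {
  cfg <- sim_config(n_participants = 20, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))

  expect_error(sim_config(n_participants = 3), "n_participants")
  expect_error(sim_config(n_participants = 10, condition_ratio = 1),
               "condition_ratio")
  bad <- default_measure_correlation(r = 0.3)
  bad[1, 2] <- bad[2, 1] <- 0.999
  bad[1, 3] <- bad[3, 1] <- -0.999
  bad[2, 3] <- bad[3, 2] <- 0.999
  expect_error(sim_config(n_participants = 10, measure_correlation = bad),
               "positive semi-definite")
})

test_that("null configuration produces no mean change in either arm", {
  eff <- default_self_report_effects()
  eff$negative <- eff$positive <- 0
  cfg <- sim_config(n_participants = 1000, seed = 5,
                    self_report_effects = eff)
  co <- generate_cohort(cfg)
  ch <- co$post - co$pre
  for (arm in 0:1) {
    sel <- co$participants$condition == arm
    m <- colMeans(ch[sel, ])
    se <- apply(ch[sel, ], 2, sd) / sqrt(sum(sel))
    expect_true(all(abs(m) < 3 * se))
  }
})

test_that("default effects reproduce the configured standardized changes", {
  cfg <- sim_config(n_participants = 10000, seed = 7)
  co <- generate_cohort(cfg)
  neg <- co$participants$condition == 0
  ch <- co$post[neg, "gratitude"] - co$pre[neg, "gratitude"]
  se <- sd(ch) / sqrt(length(ch))
  expect_lt(abs(mean(ch) - (-0.162)), 3 * se)
  # positive arm, a second measure
  pos <- !neg
  ch2 <- co$post[pos, "elevation"] - co$pre[pos, "elevation"]
  expect_lt(abs(mean(ch2) - 0.166), 3 * sd(ch2) / sqrt(length(ch2)))
})

test_that("cognitive logs respect degenerate and nominal probabilities", {
  cfg <- sim_config(
    n_participants = 4, seed = 2,
    cognitive = cognitive_params(hit_prob = c(pos = 1, neg = 1, neu = 1),
                                 fa_prob = c(pos = 0, neg = 0, neu = 0))
  )
  logs <- simulate_cognitive_logs(generate_cohort(cfg), cfg)
  rec <- logs$recognition
  expect_true(all(rec$clicked[rec$is_old]))
  expect_false(any(rec$clicked[!rec$is_old]))

  # structural invariants
  wf1 <- logs$word_find[logs$word_find$participant_id == "P001" &
                          logs$word_find$session == "pre", ]
  expect_setequal(wf1$find_order, 1:9)
  expect_true(all(diff(wf1$find_time[order(wf1$find_order)]) > 0))
  con <- logs$construal
  expect_true(all(con$rating %in% 1:7))
  expect_true(all(con$reaction_time > 0))

  # binomial fidelity at large n
  cfg2 <- sim_config(
    n_participants = 4, seed = 3,
    cognitive = cognitive_params(
      hit_prob = c(pos = 0.75, neg = 0.75, neu = 0.75),
      fa_prob = c(pos = 0.25, neg = 0.25, neu = 0.25),
      n_per_cell = 2000
    )
  )
  logs2 <- simulate_cognitive_logs(generate_cohort(cfg2), cfg2)
  rec2 <- logs2$recognition
  n_old <- sum(rec2$is_old)
  hit_rate <- mean(rec2$clicked[rec2$is_old])
  fa_rate <- mean(rec2$clicked[!rec2$is_old])
  se <- sqrt(0.75 * 0.25 / n_old)
  expect_lt(abs(hit_rate - 0.75), 3 * se)
  expect_lt(abs(fa_rate - 0.25), 3 * se)
})

test_that("simulated EEG matches its ground truth", {
  tl <- make_event_timeline(n_events = 12, seed = 1)
  clean <- sim_config(n_participants = 4, seed = 3,
                      eeg = eeg_params(blink_rate = 0, artifact_rate = 0))
  rec <- simulate_eeg(tl, clean, duration = 60)
  expect_lt(max(abs(rec$data)), 400)
  expect_identical(simulate_eeg(tl, clean, duration = 60)$data, rec$data)

  # sync pulse edge lands on the event onset sample
  tl10 <- data.frame(onset = 10, duration = 1,
                     trial_type = "emotional_memory",
                     stimulus_valence = "pos")
  rec10 <- simulate_eeg(tl10, clean, duration = 20)
  onsets <- detect_sync_events(rec10$sync, 128)
  expect_length(onsets, 1)
  expect_lte(abs(onsets - (10 * 128 + 1)), 1)

  # timeline past the recording errors
  expect_error(simulate_eeg(tl, clean, duration = 10), "beyond")

  # injected artifacts are recovered by the artifact marker
  arty <- sim_config(n_participants = 4, seed = 3,
                     eeg = eeg_params(blink_rate = 0, artifact_rate = 0.1))
  rec_a <- simulate_eeg(tl, arty, duration = 60)
  gt <- rec_a$ground_truth$artifacts
  expect_gt(nrow(gt), 3)
  mask <- mark_artifacts(rec_a)
  flagged <- 0; total <- 0
  for (i in seq_len(nrow(gt))) {
    idx <- (round(gt$start[i] * 128) + 1):round(gt$end[i] * 128)
    total <- total + length(idx)
    flagged <- flagged + sum(mask[idx, gt$channel[i]])
  }
  expect_gte(flagged / total, 0.9)
})

test_that("simulated wristband streams match their ground truth", {
  tl <- make_event_timeline(n_events = 12, seed = 1)
  base <- ans_params(lf_depth = 0, hf_depth = 0, depth_sd = 0, rr_noise = 0)
  cfg <- sim_config(n_participants = 4, seed = 3, ans = base)
  st <- simulate_wristband(tl, cfg, duration = 120)
  expect_equal(unique(round(st$rr$rr_ms, 9)), 800)

  expect_error(ans_params(hf_depth = -1), "non-negative")

  # HF power scales with the square of the modulation depth
  mk <- function(depth) {
    cfgd <- sim_config(n_participants = 4, seed = 3,
                       ans = ans_params(hf_depth = depth, lf_depth = 0,
                                        depth_sd = 0, rr_noise = 0))
    st <- simulate_wristband(tl, cfgd, duration = 300)
    hrv_band_power(st$rr, c(0.15, 0.4))
  }
  p20 <- mk(20); p40 <- mk(40)
  expect_lt(abs(p40 / p20 - 4), 0.8) # ratio 4 +/- 20%

  # absent component: HF power collapses to the noise floor
  cfg0 <- sim_config(n_participants = 4, seed = 3,
                     ans = ans_params(hf_depth = 0, lf_depth = 0,
                                      depth_sd = 0, rr_noise = 2))
  st0 <- simulate_wristband(tl, cfg0, duration = 300)
  expect_lt(hrv_band_power(st0$rr, c(0.15, 0.4)) / p20, 0.05)
})
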