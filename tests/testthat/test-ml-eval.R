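# Nested cross-validation, model families, hierarchical group evaluation.

test_that("a perfectly separable feature is classified at ceiling", {
  set.seed(1)
  y <- rep(c(0, 1), each = 50)
  x <- cbind(lab = as.numeric(y), n1 = rnorm(100))
  res <- nested_cv_classify(x, y, cv_config(n_repeats = 4, seed = 5))
  expect_equal(nrow(res$accuracy), 4) # all four model families
  expect_true(all(res$accuracy$test_accuracy == 1))
})

test_that("pure-noise features stay at chance and shuffling labels leaks nothing", {
  set.seed(2)
  x <- matrix(rnorm(200 * 10), 200)
  colnames(x) <- paste0("f", 1:10)
  y <- rep(c(0, 1), 100)
  res <- nested_cv_classify(x, y, cv_config(seed = 7,
                                            model_families = "logistic_l1"))
  n_pred <- 20 * round(200 * 0.2)
  expect_lt(abs(res$accuracy$test_accuracy - 0.5),
            chance_ci_halfwidth(n_pred))

  # informative feature + shuffled labels -> chance
  x2 <- cbind(x[, 1:3], sig = as.numeric(y))
  y_shuf <- sample(y)
  res2 <- nested_cv_classify(x2, y_shuf,
                             cv_config(seed = 8,
                                       model_families = "logistic_l1"))
  expect_lt(abs(res2$accuracy$test_accuracy - 0.5),
            chance_ci_halfwidth(n_pred))
})

test_that("results are reproducible under a fixed seed", {
  set.seed(3)
  x <- matrix(rnorm(80 * 6), 80)
  colnames(x) <- paste0("f", 1:6)
  y <- rep(c(0, 1), 40)
  cfg <- cv_config(n_repeats = 5, seed = 17,
                   model_families = c("logistic_l1", "random_forest"))
  r1 <- nested_cv_classify(x, y, cfg)
  r2 <- nested_cv_classify(x, y, cfg)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$selected, r2$selected)
})

test_that("L1 drives uninformative coefficients to zero, monotonically", {
  set.seed(4)
  n <- 150
  y <- rep(c(0, 1), n / 2)
  x <- cbind(
    sig1 = y + rnorm(n, 0, 0.5),
    sig2 = -y + rnorm(n, 0, 0.5),
    matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("noise", 1:8)))
  )
  cfg <- cv_config(seed = 9, model_families = "logistic_l1")
  be <- affectpipe:::backend_logistic(cfg)
  grid <- sort(cfg$regularization_grid) # increasing penalty
  zero_counts <- vapply(grid, function(l) {
    m <- be$fit(x, y, l)
    cf <- be$coefs(m, l)[-1]
    sum(abs(cf) < 1e-8)
  }, numeric(1))
  expect_true(all(diff(zero_counts) >= 0))
  # moderate penalty keeps the signal, kills most noise
  m <- be$fit(x, y, 0.1)
  cf <- be$coefs(m, 0.1)
  expect_true(abs(cf["sig1"]) > 0)
  expect_gte(sum(abs(cf[paste0("noise", 1:8)]) < 1e-8), 6)
})

test_that("group PCA reduces to five components and hierarchy flags signal", {
  set.seed(5)
  n <- 120
  y <- rep(c(0, 1), n / 2)
  base <- matrix(rnorm(n * 14), n, 14,
                 dimnames = list(NULL, paste0("sr", 1:14)))
  base[, 1:4] <- base[, 1:4] + outer(y, rep(0.8, 4)) # informative baseline
  expect_equal(ncol(reduce_group_pca(base, k = 5)), 5)

  noise_grp <- matrix(rnorm(n * 6), n, 6,
                      dimnames = list(NULL, paste0("ns", 1:6)))
  shift_grp <- matrix(rnorm(n * 6), n, 6,
                      dimnames = list(NULL, paste0("sh", 1:6)))
  shift_grp[, 1:3] <- shift_grp[, 1:3] + outer(y, rep(1, 3))

  cfg <- cv_config(seed = 23, n_repeats = 10,
                   model_families = "logistic_l1")
  tab <- hierarchical_evaluation(
    list(self_report = base, noise = noise_grp, shifted = shift_grp),
    y, config = cfg
  )
  expect_s3_class(tab, "hierarchical_cv")
  expect_setequal(tab$combination,
                  c("self_report", "noise", "shifted",
                    "self_report+noise", "self_report+shifted"))
  n_pred <- 10 * round(n * 0.2)
  half <- chance_ci_halfwidth(n_pred)
  noise_alone <- tab$test_accuracy[tab$combination == "noise"]
  shift_alone <- tab$test_accuracy[tab$combination == "shifted"]
  expect_lt(abs(noise_alone - 0.5), half)
  expect_gt(shift_alone, 0.5 + half)
  # an uninformative addition does not beat the baseline beyond noise
  d_noise <- tab$delta_test_vs_baseline[tab$combination ==
                                          "self_report+noise"]
  expect_lt(d_noise, 2 * half)

  # identical results regardless of group list order
  tab2 <- hierarchical_evaluation(
    list(self_report = base, shifted = shift_grp, noise = noise_grp),
    y, config = cfg
  )
  for (cmb in tab$combination) {
    expect_equal(tab$test_accuracy[tab$combination == cmb],
                 tab2$test_accuracy[tab2$combination == cmb])
  }

  # misaligned groups error
  expect_error(
    hierarchical_evaluation(list(a = base, b = noise_grp[1:50, ]), y),
    "misaligned"
  )
})

test_that("an injected alpha-band condition shift is detected end to end", {
  tl <- make_event_timeline(n_events = 10, duration = 1,
                            isi_range = c(2.75, 3.25), seed = 2)
  run_cohort <- function(effect, seed) {
    cfg <- sim_config(
      n_participants = 40, seed = seed,
      physio_effect = if (is.null(effect)) NULL else
        list(alpha_amplitude = effect),
      eeg = eeg_params(blink_rate = 0.1, artifact_rate = 0)
    )
    cohort <- generate_cohort(cfg)
    feats <- matrix(NA_real_, 40, 2,
                    dimnames = list(NULL, c("alpha_change", "theta_change")))
    for (i in 1:40) {
      cond <- cohort$participants$condition[i]
      v <- sapply(c("pre", "post"), function(ses) {
        rec <- simulate_eeg(tl, cfg, participant = i, session = ses,
                            condition = cond, duration = 45)
        pp <- preprocess_eeg(rec)
        f <- extract_event_features(pp, tl)
        c(alpha = mean(f$features$alpha_rms),
          theta = mean(f$features$theta_rms))
      })
      feats[i, ] <- v[, "post"] - v[, "pre"]
    }
    list(x = feats, y = cohort$participants$condition)
  }
  cfg_cv <- cv_config(seed = 31, model_families = "logistic_l1")
  n_pred <- 20 * round(40 * 0.2)
  half <- chance_ci_halfwidth(n_pred)

  with_shift <- run_cohort(1, seed = 61)
  acc1 <- nested_cv_classify(with_shift$x, with_shift$y,
                             cfg_cv)$accuracy$test_accuracy
  expect_gt(acc1, 0.5 + half)

  no_shift <- run_cohort(NULL, seed = 61)
  acc0 <- nested_cv_classify(no_shift$x, no_shift$y,
                             cfg_cv)$accuracy$test_accuracy
  expect_lt(abs(acc0 - 0.5), half)
})
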