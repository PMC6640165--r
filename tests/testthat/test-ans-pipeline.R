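# RR interpolation, spectral HRV, GSR decomposition, event features.

test_that("RR spline interpolation reproduces simple profiles", {
  bt <- cumsum(rep(0.8, 40))
  const <- interpolate_rr(bt, rep(800, 40))
  expect_equal(unique(round(const$rr_ms, 9)), 800)
  # no extrapolation beyond the beats
  expect_gte(min(const$time_s), bt[1])
  expect_lte(max(const$time_s), bt[40])

  lin <- interpolate_rr(bt, 700 + 5 * bt)
  expect_equal(lin$rr_ms, 700 + 5 * lin$time_s, tolerance = 1e-9)

  # sinusoidal modulation: peaks and troughs recovered within 2 ms
  t <- 0; bts <- c(); rrs <- c()
  while (t < 60) {
    rr <- 800 + 50 * sin(2 * pi * 0.25 * t)
    bts <- c(bts, t); rrs <- c(rrs, rr)
    t <- t + rr / 1000
  }
  g <- interpolate_rr(bts, rrs)
  expect_lt(abs(max(g$rr_ms) - 850), 2)
  expect_lt(abs(min(g$rr_ms) - 750), 2)

  expect_error(interpolate_rr(c(0, 1, 2), c(800, 800, 800)), "4 beats")
  expect_error(interpolate_rr(c(0, 2, 1, 3), rep(800, 4)), "increasing")
})

test_that("band powers localize tones and scale with amplitude squared", {
  tt <- seq(0.25, 300, by = 0.25)
  hf_series <- 800 + 30 * sin(2 * pi * 0.25 * tt)
  lf_series <- 800 + 30 * sin(2 * pi * 0.1 * tt)

  tot_hf <- hrv_band_power(hf_series, c(0.04, 0.4))
  expect_gte(hrv_band_power(hf_series, c(0.15, 0.4)) / tot_hf, 0.95)
  tot_lf <- hrv_band_power(lf_series, c(0.04, 0.4))
  expect_gte(hrv_band_power(lf_series, c(0.04, 0.15)) / tot_lf, 0.95)

  # Parseval: doubling the amplitude quadruples the band power
  hf2 <- 800 + 60 * sin(2 * pi * 0.25 * tt)
  ratio <- hrv_band_power(hf2, c(0.15, 0.4)) /
    hrv_band_power(hf_series, c(0.15, 0.4))
  expect_lt(abs(ratio - 4), 0.4)
  # absolute level: a tone of amplitude A carries power A^2/2
  expect_lt(abs(hrv_band_power(hf_series, c(0.15, 0.4)) - 450) / 450, 0.05)

  expect_error(hrv_band_power(hf_series, c(0.15, 3)), "Nyquist")
  expect_error(hrv_band_power(hf_series[1:32], c(0.15, 0.4)), "short")

  # band additivity: HF + LF never exceeds the total 0.04-0.4 power
  set.seed(13)
  for (i in 1:10) {
    x <- 800 + cumsum(rnorm(600, 0, 3))
    tot <- hrv_band_power(x, c(0.04, 0.4))
    expect_lte(hrv_band_power(x, c(0.04, 0.15)) +
                 hrv_band_power(x, c(0.15, 0.4)), tot + 1e-9)
  }
})

test_that("tonic/phasic stand-in reconstructs the input exactly", {
  set.seed(5)
  x <- 2 + 0.5 * sin(seq(0, 20, length.out = 2000)) + rnorm(2000, 0, 0.05)
  d <- decompose_gsr(x, rate = 20)
  expect_equal(d$tonic + d$phasic, x, tolerance = 1e-12)
  # tonic is smooth relative to the input
  expect_lt(sd(diff(d$tonic)), sd(diff(x)))
})

test_that("event features summarize windows and recover HF power", {
  ev <- data.frame(onset = c(10, 20, 30), duration = 2)
  grid20 <- seq(0.05, 60, by = 0.05)
  mkstreams <- function(value_fun) {
    bt <- cumsum(rep(0.8, 80))
    list(
      rr = interpolate_rr(bt, rep(800, 80)),
      gsr_tonic = data.frame(time_s = grid20, value = value_fun(grid20)),
      gsr_phasic = data.frame(time_s = grid20, value = 0),
      temperature = data.frame(time_s = grid20, value = 33)
    )
  }
  st_const <- mkstreams(function(t) rep(2.5, length(t)))
  f <- extract_event_ans_features(st_const, ev, hrv_window_sec = 30)
  tonic <- f[f$feature == "gsr_tonic", ]
  expect_equal(tonic$mean_amplitude, 2.5)
  expect_equal(tonic$peak_to_peak, 0)

  # sawtooth 0 -> 1 within each window has peak-to-peak 1
  saw <- mkstreams(function(t) (t %% 2) / 2)
  fs <- extract_event_ans_features(saw, ev, hrv_window_sec = 30)
  expect_equal(fs[fs$feature == "gsr_tonic", "peak_to_peak"], 0.975,
               tolerance = 0.03)

  # HF round trip from the simulator within 25% of depth^2/2
  tl <- make_event_timeline(n_events = 48, seed = 3)
  cfg <- sim_config(n_participants = 4, seed = 3,
                    ans = ans_params(hf_depth = 25, lf_depth = 0,
                                     depth_sd = 0, rr_noise = 1))
  st <- simulate_wristband(tl, cfg, duration = 260)
  fr <- extract_event_ans_features(st, tl)
  hf <- fr[fr$feature == "hf_hrv", "mean_amplitude"]
  expect_lt(abs(hf - 25^2 / 2) / (25^2 / 2), 0.25)
})

test_that("features are invariant to a joint time shift", {
  ev <- data.frame(onset = c(10, 20), duration = 2)
  bt <- cumsum(rep(0.8, 80))
  grid <- seq(0.05, 60, by = 0.05)
  set.seed(8)
  vals <- 2 + cumsum(rnorm(length(grid), 0, 0.01))
  st <- list(
    rr = interpolate_rr(bt, 800 + 10 * sin(2 * pi * 0.25 * bt)),
    gsr_tonic = data.frame(time_s = grid, value = vals),
    gsr_phasic = data.frame(time_s = grid, value = 0.1),
    temperature = data.frame(time_s = grid, value = 33)
  )
  shift <- 7.5
  st2 <- st
  for (nm in names(st2)) st2[[nm]]$time_s <- st2[[nm]]$time_s + shift
  names(st2$rr) <- names(st$rr) # keep rr_ms column name
  ev2 <- ev; ev2$onset <- ev$onset + shift
  f1 <- extract_event_ans_features(st, ev, hrv_window_sec = 30)
  f2 <- extract_event_ans_features(st2, ev2, hrv_window_sec = 30)
  expect_equal(f1$mean_amplitude, f2$mean_amplitude, tolerance = 1e-9)
  expect_equal(f1$peak_to_peak, f2$peak_to_peak, tolerance = 1e-9)
})
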