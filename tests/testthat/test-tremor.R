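test_that("the gyroscope heuristic fires on tremor-band oscillation only", {
  cfg <- test_config()
  set.seed(13)
  t <- (0:383) / cfg$fs
  noise <- matrix(rnorm(3 * 384, sd = 0.5), 3)
  # 5 Hz, 10 deg/s oscillation: all three criteria hold
  trem <- noise + c(0.8, 0.5, 0.3) %o% (10 * sin(2 * pi * 5 * t))
  expect_true(gyro_heuristic_tremor(trem, cfg))
  # slow voluntary rotation, 20 deg/s at 1 Hz: dominant frequency off-band
  slow <- noise + c(1, 0, 0) %o% (20 * sin(2 * pi * 1 * t))
  expect_false(gyro_heuristic_tremor(slow, cfg))
  # (near-)zero signal: amplitude criterion fails
  expect_false(gyro_heuristic_tremor(noise * 0.01, cfg))
  expect_error(gyro_heuristic_tremor(NULL, cfg), "modality")
})

test_that("tremor amplitude matches the closed form and is linear", {
  cfg <- test_config()
  set.seed(14)
  w <- osc_window(5, 0.2, u = c(0.3, 0.8, 0.5), noise_sd = 0.0005)
  expect_equal(tremor_amplitude(w, cfg), 0.2 / sqrt(2), tolerance = 0.05)
  # pure rest noise stays far below tremor scale
  rest <- osc_window(5, 0, noise_sd = 0.002)
  expect_lt(tremor_amplitude(rest, cfg), 0.01)
  # linear in oscillation amplitude
  w1 <- osc_window(5, 0.1, u = c(1, 0.2, 0), phase = 0.7)
  w2 <- osc_window(5, 0.3, u = c(1, 0.2, 0), phase = 0.7)
  expect_equal(tremor_amplitude(w2, cfg) / tremor_amplitude(w1, cfg), 3,
               tolerance = 0.01)
  expect_error(tremor_amplitude(w[, 1:100], cfg), "length error")
})

test_that("visit tremor summary computes constancy and the amplitude percentile", {
  cfg <- test_config()
  flags <- c(rep(TRUE, 30), rep(FALSE, 870))
  amps <- ifelse(flags, 0.15, NA_real_)
  s <- summarize_tremor_visit(flags, amps, cfg)
  expect_equal(s$constancy_pct, 100 * 30 / 900, tolerance = 1e-12)
  expect_equal(s$amplitude_g, 0.15)
  # percentile equals the sort-based definition (linear interpolation)
  set.seed(15)
  a <- runif(40, 0, 0.4)
  f <- rep(TRUE, 40)
  s2 <- summarize_tremor_visit(f, a, cfg)
  h <- (40 - 1) * 0.85 + 1
  srt <- sort(a)
  oracle <- srt[floor(h)] + (h - floor(h)) * (srt[ceiling(h)] - srt[floor(h)])
  expect_equal(s2$amplitude_g, oracle, tolerance = 1e-12)
  expect_error(summarize_tremor_visit(logical(0), numeric(0), cfg), "empty")
  # rest-denominator switch
  cfg2 <- test_config(constancy_all_windows = FALSE)
  fl <- c(TRUE, FALSE, NA, NA)
  expect_equal(summarize_tremor_visit(fl, c(0.1, NA, NA, NA), cfg2)$constancy_pct,
               50)
})

test_that("heuristic labelling builds a coherent training set", {
  cfg <- test_config()
  # PD visit with a scripted 30% tremor fraction
  script <- segment_script(c("REST", "TREMOR", "REST", "TREMOR", "REST"),
                           c(21, 18, 21, 9, 21))
  sim <- simulate_recording(script, 16, cfg, subject_id = "PD01", cohort = "PD")
  hc <- simulate_recording(segment_script(c("REST", "MOVE"), c(45, 45)), 17,
                           cfg, subject_id = "HC01", cohort = "HC")
  ts <- build_tremor_training_set(list(sim$recording), list(hc$recording),
                                  cfg, balance = FALSE)
  pos_frac <- sum(ts$label == "TREMOR") / 30  # 30 windows in the PD visit
  expect_equal(pos_frac, 0.3, tolerance = 0.05 / 0.3)
  expect_equal(ncol(ts), 67)
  bal <- build_tremor_training_set(list(sim$recording), list(hc$recording), cfg)
  expect_equal(sum(bal$label == "TREMOR"), sum(bal$label == "NOTREMOR"))
  # HC-only input cannot provide positives
  expect_error(build_tremor_training_set(list(hc$recording), list(), cfg),
               "class-coverage")
})

test_that("tremor prediction requires the tremor catalog", {
  models <- fixture_models()
  expect_error(predict_tremor(models$gait, data.frame()), "schema error")
})
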