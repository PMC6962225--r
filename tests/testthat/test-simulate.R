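test_that("rest is gravity plus noise and tremor has the scripted spectral peak", {
  cfg <- test_config()
  rest <- simulate_recording(segment_script("REST", 30), 22, cfg)
  vm <- vector_magnitude(rest$recording$accel)
  expect_equal(mean(vm), 1, tolerance = 0.01)

  trem <- simulate_recording(segment_script("TREMOR", 30, tremor_hz = 5), 23, cfg)
  grid <- segment_windows(trem$recording, cfg)
  w <- trem$recording$accel[, 385:768]
  bp <- butterworth_filter(w, 3, cfg$tremor_band_hz, cfg$fs)
  ps <- power_spectrum(vector_magnitude(bp) - mean(vector_magnitude(bp)), cfg$fs)
  # rectified magnitude of a 5 Hz oscillation peaks at 2 x 5 Hz; the
  # per-axis spectra peak at 5 Hz
  psx <- power_spectrum(bp[1, ], cfg$fs)
  expect_equal(psx$freq[which.max(psx$power)], 5, tolerance = 0.34 / 5)
})

test_that("simulation is reproducible and ground truth is bookkept exactly", {
  cfg <- test_config()
  script <- segment_script(c("REST", "TREMOR", "MOVE", "GAIT"), c(6, 9, 6, 9))
  a <- simulate_recording(script, 24, cfg)
  b <- simulate_recording(script, 24, cfg)
  expect_identical(a$recording$accel, b$recording$accel)
  expect_identical(a$recording$gyro, b$recording$gyro)
  c2 <- simulate_recording(script, 25, cfg)
  expect_false(identical(a$recording$accel, c2$recording$accel))

  # state durations sum exactly to the recording duration
  expect_equal(length(a$truth$state), ncol(a$recording$accel))
  expect_equal(as.vector(table(a$truth$state)[c("REST", "TREMOR", "MOVE", "GAIT")]),
               c(6, 9, 6, 9) * cfg$fs)
  expect_equal(max(a$truth$intervals$end_s), 30)
})

test_that("each state's spectral content sits in its design band", {
  cfg <- test_config()
  sim <- simulate_recording(segment_script(c("TREMOR", "MOVE", "GAIT"),
                                           c(30, 30, 30)), 26, cfg)
  grid <- segment_windows(sim$recording, cfg)
  domfreq_of <- function(k) {
    w <- sim$recording$accel[, grid$starts[k]:(grid$starts[k] + 383)]
    specs <- lapply(1:3, function(a) power_spectrum(w[a, ], cfg$fs))
    p <- Reduce(`+`, lapply(specs, `[[`, "power"))
    specs[[1]]$freq[-1][which.max(p[-1])]
  }
  state_of <- sim$truth$state[grid$starts + 192]
  trem_f <- domfreq_of(which(state_of == "TREMOR")[3])
  expect_true(trem_f >= 3.5 && trem_f <= 7.5)
  move_f <- domfreq_of(which(state_of == "MOVE")[3])
  expect_lt(move_f, 3.5)
  gait_f <- domfreq_of(which(state_of == "GAIT")[3])
  expect_lt(gait_f, 3.5)
})

test_that("script validation rejects out-of-range parameters", {
  expect_error(segment_script("TREMOR", 10, tremor_hz = 12), "script error")
  expect_error(segment_script("REST", -5), "script error")
  expect_error(segment_script("GAIT", 10, cadence_spm = 0), "script error")
  expect_error(segment_script("MOVE", 10, jerkiness = 2), "script error")
})

test_that("cohorts honor severity parameters and scale with motor state", {
  cfg <- test_config()
  hc <- simulate_cohort(4, 0, seed = 27, config = cfg, visit_s = 60)
  for (s in hc) {
    expect_equal(sum(s$truth$state == "TREMOR"), 0)
    expect_identical(s$recording$cohort, "HC")
  }
  pd <- simulate_cohort(0, 3, seed = 28, config = cfg, visit_s = 180,
                        off_scale = 1.5)
  expect_length(pd, 6)
  for (i in seq(1, 6, by = 2)) {
    on <- pd[[i]]; off <- pd[[i + 1]]
    expect_identical(on$params$subject_id, off$params$subject_id)
    # OFF visit: strictly higher scripted tremor amplitude
    expect_gt(off$params$tremor_amp_g, on$params$tremor_amp_g)
    # realized tremor fraction tracks the constancy parameter
    frac <- mean(on$truth$state == "TREMOR")
    expect_equal(frac, on$params$constancy, tolerance = 0.05 / max(on$params$constancy, 0.05))
  }
  expect_error(simulate_cohort(1, 0, seed = 1), "script error")
})
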