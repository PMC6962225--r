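test_that("window measures follow the closed forms", {
  cfg <- test_config()
  # 1 Hz movement at 0.3 g: band-passed vm RMS near A/sqrt(2)
  w <- osc_window(1, 0.3, u = c(1, 0.2, 0.1))
  m <- brady_window_measures(w, cfg)
  expect_equal(m$rms_g, 0.3 / sqrt(2), tolerance = 0.05)
  # halving the amplitude halves the RMS
  m2 <- brady_window_measures(osc_window(1, 0.15, u = c(1, 0.2, 0.1)), cfg)
  expect_equal(m$rms_g / m2$rms_g, 2, tolerance = 0.02)
  # hesitant movement (in-band corrective accelerations) raises the jerk
  # measure at near-equal RMS
  t <- (0:383) / cfg$fs
  u <- c(1, 0.3, 0.2) / sqrt(sum(c(1, 0.3, 0.2)^2))
  smooth <- c(0, 0, 1) %o% rep(1, 384) + u %o% (0.3 * sin(2 * pi * 1 * t))
  halting <- c(0, 0, 1) %o% rep(1, 384) +
    u %o% (0.3 * sin(2 * pi * 1 * t) + 0.15 * sin(2 * pi * 3.1 * t + 1))
  expect_gt(brady_window_measures(halting, cfg)$msj,
            brady_window_measures(smooth, cfg)$msj)
})

test_that("eligibility is exactly hand movement without gait or exclusion", {
  set.seed(18)
  for (rep in 1:50) {
    n <- sample(5:60, 1)
    hm <- sample(c("HM", "NHM"), n, replace = TRUE)
    gait <- sample(c(TRUE, FALSE, NA), n, replace = TRUE)
    excl <- sample(c(TRUE, FALSE), n, replace = TRUE)
    got <- eligible_brady_windows(hm, gait, excl)
    oracle <- vapply(seq_len(n), function(i) {
      hm[i] == "HM" && !(isTRUE(gait[i])) && !excl[i]
    }, logical(1))
    expect_identical(got, oracle)
  }
})

test_that("no-movement statistics match run-length brute force", {
  cfg <- test_config()
  s <- no_movement_statistics(c("NHM", "NHM", "HM", "NHM"), config = cfg)
  expect_equal(s$pct_time_no_movement, 75)
  expect_equal(s$n_bouts, 2)
  expect_equal(s$mean_no_movement_bout_s, 4.5)

  s2 <- no_movement_statistics(rep("HM", 6), config = cfg)
  expect_equal(s2$pct_time_no_movement, 0)
  expect_false(s2$has_bouts)
  expect_equal(s2$mean_no_movement_bout_s, 0)

  set.seed(19)
  for (rep in 1:50) {
    n <- sample(4:80, 1)
    hm <- sample(c("HM", "NHM"), n, replace = TRUE)
    excl <- runif(n) < 0.2
    if (all(excl)) excl[1] <- FALSE
    got <- no_movement_statistics(hm, excl, cfg)
    # brute force: walk the sequence
    bouts <- integer(0); run <- 0L
    for (i in seq_len(n)) {
      if (!excl[i] && hm[i] == "NHM") {
        run <- run + 1L
      } else {
        if (run > 0) bouts <- c(bouts, run)
        run <- 0L
      }
    }
    if (run > 0) bouts <- c(bouts, run)
    expect_equal(got$pct_time_no_movement,
                 100 * sum(hm[!excl] == "NHM") / sum(!excl))
    expect_equal(got$n_bouts, length(bouts))
    expect_equal(got$mean_no_movement_bout_s,
                 if (length(bouts)) mean(bouts) * 3 else 0)
  }
})

test_that("visit summary aggregates eligible windows and flags missing data", {
  cfg <- test_config()
  hm <- c("HM", "HM", "NHM", "HM")
  gait <- c(FALSE, TRUE, NA, FALSE)
  rms_g <- c(0.2, NA, NA, 0.2)
  msj <- c(30, NA, NA, 30)
  s <- summarize_brady_visit(rms_g, msj, hm, gait, config = cfg)
  expect_equal(s$amplitude_mean_g, 0.2)
  expect_equal(s$smoothness_msj_p95, 30)
  expect_equal(s$n_eligible, 2)
  # no eligible windows: missing, never zero
  s0 <- summarize_brady_visit(rep(NA_real_, 3), rep(NA_real_, 3),
                              rep("NHM", 3), rep(NA, 3), config = cfg)
  expect_true(is.na(s0$amplitude_mean_g))
  expect_false(s0$has_measures)
  # percentile matches order statistics
  set.seed(20)
  v <- runif(30, 10, 90)
  sp <- summarize_brady_visit(rep(0.1, 30), v, rep("HM", 30),
                              rep(FALSE, 30), config = cfg)
  expect_equal(sp$smoothness_msj_p95,
               unname(quantile(v, 0.95, type = 7)), tolerance = 1e-12)
})

test_that("score model recovers planted affine relations", {
  set.seed(21)
  amp <- runif(30, 0.05, 0.35)
  b_true <- -24
  score <- pmin(pmax(9.5 + b_true * amp + rnorm(30, sd = 0.4), 0), 12)
  m <- fit_score_model(amp, score, subject_id = rep(1:15, each = 2))
  expect_lt(abs(coef(m)["amplitude_mean_g"] - b_true), 3 * m$se[2])
  expect_lt(abs(coef(m)["(Intercept)"] - 9.5), 3 * m$se[1])
  expect_lt(coef(m)["amplitude_mean_g"], 0)  # sign recovery

  # zero-noise: exact affine relation, leave-one-subject-out error vanishes
  score0 <- 9.5 + b_true * amp
  m0 <- fit_score_model(amp, score0, subject_id = rep(1:15, each = 2))
  expect_lt(m0$loso_rmse, 1e-6)

  # predictions are clipped to the score range
  expect_equal(unname(predict(m0, 10)), 0)
  expect_equal(unname(predict(m0, -10)), 12)

  expect_error(fit_score_model(rep(0.2, 10), rnorm(10)), "degenerate|fit error")
  expect_error(fit_score_model(c(0.1, 0.2), c(1, 2)), "data-size")
})
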