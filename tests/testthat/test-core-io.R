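test_that("sensor CSV round trip is lossless to declared precision", {
  cfg <- test_config()
  sim <- simulate_recording(segment_script(c("REST", "MOVE"), c(6, 6)), 3, cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(sim$recording, path)
  back <- read_recording(path, fs = cfg$fs)
  expect_equal(back$accel, sim$recording$accel, tolerance = 1e-9)
  expect_equal(back$gyro, sim$recording$gyro, tolerance = 1e-9)
  expect_equal(ncol(back$accel), ncol(sim$recording$accel))
})

test_that("reader rejects malformed files", {
  t <- (0:383) / 128
  df <- data.frame(time_s = t, ax_g = 0, ay_g = 0, az_g = 1)
  path <- withr::local_tempfile(fileext = ".csv")

  write.csv(df[, -2], path, row.names = FALSE)
  expect_error(read_recording(path), "schema error")

  df_gap <- df
  df_gap$time_s[200:384] <- df_gap$time_s[200:384] + 0.5
  write.csv(df_gap, path, row.names = FALSE)
  expect_error(read_recording(path), "sampling|non-uniform")

  df_bad <- df
  df_bad$ax_g[5] <- NA
  write.csv(df_bad, path, row.names = FALSE)
  expect_error(read_recording(path), "non-finite")

  write.csv(df, path, row.names = FALSE)
  rec <- read_recording(path)
  expect_s3_class(rec, "inertial_recording")
  expect_equal(ncol(rec$accel), 384)
})

test_that("windowing follows the floor rule and drops the trailing remainder", {
  cfg <- test_config()
  expect_length(segment_windows(45 * 60 * 128, cfg)$starts, 900)
  grid <- segment_windows(400, cfg)
  expect_length(grid$starts, 1)
  expect_equal(grid$n_per_window, 384)
  expect_error(segment_windows(383, cfg), "too short")
  # window count equals floor(duration / window_length) across durations
  for (n in c(384, 500, 768, 1000, 12345)) {
    expect_length(segment_windows(n, cfg)$starts, n %/% 384)
  }
  # windows are disjoint and contiguous
  g <- segment_windows(3840, cfg)
  expect_equal(diff(g$starts), rep(384, length(g$starts) - 1))
})

test_that("interval majority labelling is strict at exactly half", {
  cfg <- test_config()
  grid <- segment_windows(384 * 4, cfg)
  # 2.0 s of window 1 -> positive (2/3 > 1/2)
  iv <- interval_set(0.5, 2.5, "X")
  expect_true(labels_from_intervals(grid, iv, "X")[1])
  # exactly 1.5 s -> negative ("more than 50%" is strict)
  iv2 <- interval_set(0.0, 1.5, "X")
  expect_false(labels_from_intervals(grid, iv2, "X")[1])
})

test_that("interval labelling matches a per-sample brute-force counter", {
  cfg <- test_config()
  fs <- cfg$fs
  n_win <- 8
  grid <- segment_windows(384 * n_win, cfg)
  set.seed(42)
  for (rep in 1:30) {
    k <- sample(1:6, 1)
    starts <- sort(runif(k, 0, n_win * 3 - 0.5))
    ends <- starts + runif(k, 0.1, 4)
    ends <- pmin(ends, n_win * 3)
    iv <- interval_set(starts, ends, "P")
    got <- labels_from_intervals(grid, iv, "P")
    # brute force: count covered sample midpoints per window
    tmid <- ((seq_len(384 * n_win) - 1) + 0.5) / fs
    covered <- rep(FALSE, length(tmid))
    for (i in seq_len(k)) covered <- covered | (tmid >= starts[i] & tmid < ends[i])
    frac <- vapply(seq_len(n_win), function(w) {
      mean(covered[((w - 1) * 384 + 1):(w * 384)])
    }, numeric(1))
    # midpoint sampling quantizes overlap to 1/384: compare away from the tie
    decided <- abs(frac - 0.5) > 1 / 200
    expect_equal(got[decided], (frac > 0.5)[decided])
  }
})

test_that("labelling is invariant to splitting an interval into abutting pieces", {
  cfg <- test_config()
  grid <- segment_windows(384 * 6, cfg)
  whole <- interval_set(2.2, 13.7, "P")
  pieces <- interval_set(c(2.2, 5.0, 9.3), c(5.0, 9.3, 13.7), "P")
  expect_identical(labels_from_intervals(grid, whole, "P"),
                   labels_from_intervals(grid, pieces, "P"))
})

test_that("recording invariants are enforced", {
  t <- (0:383) / 128
  a <- rbind(0, 0, rep(1, 384))
  expect_error(inertial_recording(t, a, gyro = a[, 1:100]), "length")
  expect_error(inertial_recording(t[1:100], a), "length")
  expect_error(inertial_recording(t, a, fs = -1), "positive")
  expect_error(interval_set(2, 1, "X"), "start_s < end_s")
  expect_error(interval_set(0, 99, "X", duration_s = 10), "outside")
})
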