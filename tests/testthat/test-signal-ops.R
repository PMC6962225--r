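test_that("vector magnitude is the Euclidean norm and rotation-invariant", {
  expect_equal(vector_magnitude(cbind(c(0, 0, 1))), 1)
  expect_equal(vector_magnitude(cbind(c(0.6, 0.8, 0))), 1)
  set.seed(1)
  x <- matrix(rnorm(3 * 50), 3)
  for (i in 1:20) {
    R <- random_rotation()
    expect_equal(vector_magnitude(R %*% x), vector_magnitude(x),
                 tolerance = 1e-12)
  }
})

test_that("zero-phase Butterworth filters have the designed gain", {
  fs <- 128
  t <- (0:383) / fs
  s5 <- sin(2 * pi * 5 * t)
  central <- 39:345  # central 80% of the window

  # 5 Hz through the 3.5-7.5 Hz band-pass: passband, amplitude preserved
  bp <- butterworth_filter(s5, 3, c(3.5, 7.5), fs)
  expect_lt(max(abs(bp[central] - s5[central])), 0.05)

  # 5 Hz through the 3 Hz low-pass: deep stopband of the squared response
  lp <- butterworth_filter(s5, 6, 3, fs)
  expect_lt(max(abs(lp[central])), 0.25)

  expect_equal(butterworth_filter(rep(0, 384), 4, c(0.25, 3.5), fs),
               rep(0, 384))
  expect_error(butterworth_filter(s5, 2, 70, fs), "fs/2")
  expect_error(butterworth_filter(s5[1:10], 6, 3, fs), "too short")
})

test_that("first principal component has the defining properties", {
  t <- (0:127) / 128
  x <- sin(2 * pi * 2 * t)
  w <- rbind(x, 0, 0)
  # single-axis signal: projection recovers the mean-centered axis
  expect_equal(pca_first_component(w), x - mean(x), tolerance = 1e-9)

  set.seed(2)
  for (i in 1:20) {
    w <- matrix(rnorm(3 * 64), 3)
    p <- pca_first_component(w)
    centered <- w - rowMeans(w)
    # Rayleigh property: projection variance >= any channel variance
    expect_gte(var(p) + 1e-12, max(apply(centered, 1, var)))
    # rotation invariance of |projection|
    R <- random_rotation()
    expect_equal(abs(pca_first_component(R %*% w)), abs(p),
                 tolerance = 1e-9)
  }
  expect_error(pca_first_component(matrix(1, 3, 10)), "degenerate")
})

test_that("rolling coefficient of variation matches its definition exactly", {
  expect_equal(rolling_cov(rep(3, 400), 1, 128), rep(0, 400))
  set.seed(3)
  for (i in 1:100) {
    n <- sample(130:300, 1)
    x <- abs(rnorm(n, mean = 1, sd = 0.2)) + 0.1
    got <- rolling_cov(x, 1, 128)
    k <- 128
    oracle <- vapply(k:n, function(j) {
      seg <- x[(j - k + 1):j]
      sd(seg) / max(abs(mean(seg)), 1e-6)
    }, numeric(1))
    expect_equal(got[k:n], oracle, tolerance = 1e-12)
    expect_equal(got[1:(k - 1)], rep(oracle[1], k - 1))
    # scale invariance
    expect_equal(rolling_cov(5 * x, 1, 128), got, tolerance = 1e-9)
  }
  expect_error(rolling_cov(1:10, 1, 128), "shorter")
})

test_that("rms has the closed forms and the concatenation identity", {
  t <- (0:383) / 128
  expect_equal(rms(sin(2 * pi * 4 * t)), 1 / sqrt(2), tolerance = 0.005)
  expect_equal(rms(rep(-2.5, 10)), 2.5)
  set.seed(4)
  a <- rnorm(100); b <- rnorm(57)
  expect_equal(rms(c(a, b))^2,
               (100 * rms(a)^2 + 57 * rms(b)^2) / 157, tolerance = 1e-12)
  expect_error(rms(numeric(0)), "empty")
})

test_that("scaled mean squared jerk is amplitude-invariant and frequency-monotone", {
  fs <- 128
  t <- (0:383) / fs
  msj_of <- function(a, f) scaled_mean_squared_jerk(1 + a * sin(2 * pi * f * t), fs)
  # amplitude cancels (max normalization includes the 1 g offset, so compare
  # pure oscillations)
  expect_equal(scaled_mean_squared_jerk(0.1 * sin(2 * pi * 2 * t), fs),
               scaled_mean_squared_jerk(0.7 * sin(2 * pi * 2 * t), fs),
               tolerance = 1e-9)
  # monotone in frequency for same-amplitude sinusoids
  expect_lt(msj_of(0.3, 1), msj_of(0.3, 3))
  # square-wave micro-halts raise the value
  smooth <- 1 + 0.3 * sin(2 * pi * 1 * t)
  gate <- as.numeric(sin(2 * pi * 1.2 * t) > -0.2)
  halting <- 1 + 0.3 * sin(2 * pi * 1 * t) * gate
  expect_gt(scaled_mean_squared_jerk(halting, fs),
            scaled_mean_squared_jerk(smooth, fs))
  expect_error(scaled_mean_squared_jerk(rep(0, 10), fs), "degenerate")
})

test_that("signal operators are deterministic", {
  set.seed(5)
  x <- matrix(rnorm(3 * 384), 3)
  expect_identical(butterworth_filter(x, 1, c(0.25, 3), 128),
                   butterworth_filter(x, 1, c(0.25, 3), 128))
  expect_identical(pca_first_component(x), pca_first_component(x))
  expect_identical(rolling_cov(abs(x[1, ]) + 1, 1, 128),
                   rolling_cov(abs(x[1, ]) + 1, 1, 128))
})
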