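test_that("Kruskal-Wallis matches rank arithmetic on separated groups", {
  # fully separated ranks: H equals its closed-form maximum
  v <- c(1, 2, 3, 11, 12, 13, 21, 22, 23)
  g <- rep(1:3, each = 3)
  N <- 9
  rbar <- c(2, 5, 8)
  H_max <- 12 / (N * (N + 1)) * sum(3 * (rbar - (N + 1) / 2)^2)
  kw <- kruskal_wallis(v, g)
  expect_equal(kw$statistic, H_max, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  # invariance to permutation within groups
  expect_equal(kruskal_wallis(c(3, 2, 1, 13, 12, 11, 23, 21, 22), g)$statistic,
               kw$statistic)
  expect_error(kruskal_wallis(1:5, rep(1, 5)), "grouping")
})

test_that("Conover-Iman tables have the FDR properties", {
  set.seed(29)
  v <- c(rnorm(8), rnorm(8) + 3, rnorm(8) + 6)
  g <- rep(1:3, each = 8)
  tab <- conover_iman_fdr(v, g)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$p_adj >= tab$p_raw - 1e-15))
  expect_true(all(tab$significant))
  # k = 2: single pair, rejection consistent with the rank-sum direction
  v2 <- c(rnorm(10), rnorm(10) + 4)
  tab2 <- conover_iman_fdr(v2, rep(1:2, each = 10))
  expect_equal(nrow(tab2), 1)
  expect_lt(tab2$p_adj, 0.05)
  expect_lt(tab2$t, 0)
  expect_error(conover_iman_fdr(1:4, rep(1, 4)), "grouping")
})

test_that("paired Wilcoxon detects shifts and rejects degenerate input", {
  set.seed(30)
  x <- rnorm(20)
  y <- x + 1.5 + rnorm(20, sd = 0.3)
  w <- wilcoxon_paired(x, y)
  expect_lt(w$p_value, 0.01)
  # cross-check against the exact null distribution at small n: a complete
  # one-sided shift of n = 6 gives the extreme two-sided exact p 2/2^6
  x6 <- 1:6
  y6 <- x6 + seq(0.5, 3, length.out = 6)
  expect_equal(wilcoxon_paired(x6, y6)$p_value, 2 / 64, tolerance = 1e-12)
  expect_error(wilcoxon_paired(1:5, 1:5), "degenerate")
  expect_error(wilcoxon_paired(1:4, 1:5), "equal length")
})

test_that("weighted kappa matches the contingency-table formula to 1e-12", {
  expect_equal(weighted_kappa_linear(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4)), 1)
  r1 <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 2)
  r2 <- c(0, 1, 1, 2, 2, 2, 0, 1, 1, 2)
  O <- table(factor(r1, levels = 0:2), factor(r2, levels = 0:2)) / 10
  E <- outer(rowSums(O), colSums(O))
  w <- abs(outer(0:2, 0:2, "-")) / 2
  expect_equal(weighted_kappa_linear(r1, r2, 0:2),
               1 - sum(w * O) / sum(w * E), tolerance = 1e-12)
  # independent uniform ratings: kappa near zero
  set.seed(31)
  a <- sample(0:4, 4000, replace = TRUE)
  b <- sample(0:4, 4000, replace = TRUE)
  expect_lt(abs(weighted_kappa_linear(a, b, 0:4)), 0.05)
  expect_error(weighted_kappa_linear(rep(2, 5), rep(2, 5)), "degenerate")
})

test_that("agreement ICC matches theory and is sensitive to rater offsets", {
  expect_equal(icc_agreement(cbind(1:10, 1:10))$icc, 1)
  # known variance ratio: ICC -> sigma_s^2 / (sigma_s^2 + sigma_e^2) = 0.8
  set.seed(32)
  iccs <- replicate(40, {
    subj <- rnorm(40, sd = 2)
    icc_agreement(cbind(subj + rnorm(40), subj + rnorm(40),
                        subj + rnorm(40)))$icc
  })
  expect_equal(mean(iccs), 0.8, tolerance = 0.05)
  # one CI computed on a fixed table brackets its point estimate
  subj <- rnorm(30, sd = 2)
  m <- cbind(subj + rnorm(30), subj + rnorm(30))
  r <- icc_agreement(m)
  expect_true(r$ci[1] < r$icc && r$icc < r$ci[2])
  # absolute agreement: adding a constant offset to one rater lowers ICC
  expect_gt(icc_agreement(m)$icc,
            icc_agreement(cbind(m[, 1], m[, 2] + 2.5))$icc)
  expect_error(icc_agreement(matrix(1, 6, 2)), "degenerate")
})

test_that("the rater-agreement report dispatches kappa and ICC by item type", {
  set.seed(33)
  subj <- sprintf("S%02d", 1:20)
  base <- sample(0:4, 20, replace = TRUE)
  cont <- runif(20, 0, 12)
  ratings <- rbind(
    data.frame(subject_id = subj, rater = "live", item = "tremor_constancy",
               score = base),
    data.frame(subject_id = subj, rater = "video1", item = "tremor_constancy",
               score = pmin(pmax(base + sample(-1:1, 20, TRUE), 0), 4)),
    data.frame(subject_id = subj, rater = "live", item = "hand_brady",
               score = cont),
    data.frame(subject_id = subj, rater = "video1", item = "hand_brady",
               score = pmin(pmax(cont + rnorm(20), 0), 12)))
  rep <- rater_agreement(ratings)
  expect_identical(rep$tremor_constancy$type, "weighted_kappa")
  expect_identical(rep$hand_brady$type, "icc_agreement")
  expect_true(rep$tremor_constancy$pairs$kappa[1] > 0)
  expect_true(rep$hand_brady$icc > 0)
})

test_that("statistics are invariant to observation order", {
  set.seed(34)
  v <- rnorm(24); g <- rep(1:3, each = 8)
  perm <- sample(24)
  expect_equal(kruskal_wallis(v[perm], g[perm])$statistic,
               kruskal_wallis(v, g)$statistic)
  tab1 <- conover_iman_fdr(v, g)
  tab2 <- conover_iman_fdr(v[perm], g[perm])
  expect_equal(tab1$p_adj, tab2$p_adj, tolerance = 1e-12)
})
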