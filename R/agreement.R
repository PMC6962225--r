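#' Kruskal-Wallis omnibus test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-squared approximation on
#' `k - 1` degrees of freedom (via [stats::kruskal.test()]).
#'
#' @param values Numeric observations.
#' @param group Group of each observation (>= 2 groups).
#' @return List: `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2)
    stop("grouping error: need at least 2 groups", call. = FALSE)
  if (length(values) < 3)
    stop("grouping error: need at least 3 observations", call. = FALSE)
  kt <- stats::kruskal.test(values, group)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Conover-Iman pairwise post hoc tests with FDR correction
#'
#' The standard tie-corrected Conover-Iman procedure on pooled ranks: for
#' groups i, j the statistic is
#' `t = (Ri - Rj) / sqrt(S2 * (N - 1 - H)/(N - k) * (1/ni + 1/nj))`
#' with `S2` the tie-corrected variance of the pooled ranks and `H` the
#' Kruskal-Wallis statistic, referred to a t distribution on `N - k`
#' degrees of freedom. Raw two-sided p values are adjusted across all pairs
#' by Benjamini-Hochberg false-discovery-rate correction.
#'
#' @param values Numeric observations.
#' @param group Group of each observation.
#' @param alpha Significance level recorded in the table.
#' @return Data frame: `group1`, `group2`, `t`, `p_raw`, `p_adj`,
#'   `significant`.
#' @export
conover_iman_fdr <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  k <- nlevels(group)
  if (k < 2) stop("grouping error: need at least 2 groups", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  H <- kruskal_wallis(values, group)$statistic
  rbar <- tapply(r, group, mean)
  n <- tabulate(group)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  scale <- S2 * (N - 1 - H) / (N - k)
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    denom <- sqrt(scale * (1 / n[i] + 1 / n[j]))
    tstat <- if (denom > 0) (rbar[i] - rbar[j]) / denom else 0
    c(t = unname(tstat),
      p = 2 * stats::pt(-abs(unname(tstat)), df = N - k))
  })
  p_adj <- stats::p.adjust(res["p", ], method = "BH")
  data.frame(group1 = levels(group)[pairs[1, ]],
             group2 = levels(group)[pairs[2, ]],
             t = res["t", ], p_raw = res["p", ], p_adj = p_adj,
             significant = p_adj <= alpha, row.names = NULL)
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (Wilcoxon's convention). The exact
#' distribution is used for up to 25 non-zero, untied differences; the
#' normal approximation with tie correction otherwise (via
#' [stats::wilcox.test()]).
#'
#' @param x,y Paired numeric vectors of equal length.
#' @return List: `statistic` (V, sum of positive signed ranks), `p_value`,
#'   `n_used` (pairs after dropping zeros).
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y))
    stop("paired samples must have equal length", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  if (!length(d))
    stop("degenerate error: all paired differences are zero", call. = FALSE)
  exact <- length(d) <= 25 && !anyDuplicated(abs(d))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_used = length(d))
}

#' Linearly weighted Cohen's kappa
#'
#' Chance-corrected agreement between two raters on an ordinal scale
#' `0..K`, with linear disagreement weights `w_ij = |i - j| / K`:
#' `kappa = 1 - sum(w * O) / sum(w * E)` where `O` is the observed and `E`
#' the chance-expected contingency distribution.
#'
#' @param r1,r2 Integer ratings of the same items by two raters.
#' @param categories Full ordinal category range (default `0:max`).
#' @return Kappa in `[-1, 1]`.
#' @export
weighted_kappa_linear <- function(r1, r2, categories = NULL) {
  if (length(r1) != length(r2))
    stop("ratings must have equal length", call. = FALSE)
  if (is.null(categories)) categories <- min(c(r1, r2)):max(c(r1, r2))
  if (length(categories) < 2)
    stop("degenerate error: a single category is present for both raters",
         call. = FALSE)
  f1 <- factor(r1, levels = categories)
  f2 <- factor(r2, levels = categories)
  O <- table(f1, f2) / length(r1)
  E <- outer(rowSums(O), colSums(O))
  K <- length(categories) - 1
  w <- abs(outer(seq_along(categories), seq_along(categories), "-")) / K
  we <- sum(w * E)
  if (we == 0)
    stop("degenerate error: no chance-expected disagreement", call. = FALSE)
  1 - sum(w * O) / we
}

#' Agreement intraclass correlation, ICC(A,1)
#'
#' Single-rater absolute-agreement ICC from a two-way model (subjects x
#' raters), computed from the ANOVA mean squares, with the F-based 95%
#' confidence interval. Rows with missing ratings are dropped (complete
#' cases only).
#'
#' @param table Numeric matrix, subjects in rows, raters in columns (>= 2
#'   raters).
#' @param conf_level Confidence level of the interval.
#' @return List: `icc`, `ci` (length-2), `n_subjects`, `n_raters`, and the
#'   mean squares `msr`, `msc`, `mse`.
#' @export
icc_agreement <- function(table, conf_level = 0.95) {
  m <- as.matrix(table)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  ns <- nrow(m); nr <- ncol(m)
  if (nr < 2) stop("need at least 2 raters", call. = FALSE)
  if (ns < 2) stop("need at least 2 subjects", call. = FALSE)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_r <- nr * sum((row_m - grand)^2)
  ss_c <- ns * sum((col_m - grand)^2)
  ss_t <- sum((m - grand)^2)
  ss_e <- ss_t - ss_r - ss_c
  msr <- ss_r / (ns - 1)
  msc <- ss_c / (nr - 1)
  mse <- ss_e / ((ns - 1) * (nr - 1))
  if (msr <= mse && msr < 1e-12)
    stop("degenerate error: no between-subject variance", call. = FALSE)
  icc <- (msr - mse) / (msr + (nr - 1) * mse + nr / ns * (msc - mse))
  alpha <- 1 - conf_level
  a <- (nr * icc) / (ns * (1 - icc))
  b <- 1 + (nr * icc * (ns - 1)) / (ns * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (nr - 1) + (b * mse)^2 / ((ns - 1) * (nr - 1)))
  fl <- stats::qf(1 - alpha / 2, ns - 1, v)
  fu <- stats::qf(1 - alpha / 2, v, ns - 1)
  lower <- ns * (msr - fl * mse) /
    (fl * (nr * msc + (nr * ns - nr - ns) * mse) + ns * msr)
  upper <- ns * (fu * msr - mse) /
    (nr * msc + (nr * ns - nr - ns) * mse + ns * fu * msr)
  list(icc = icc, ci = c(lower, upper), n_subjects = ns, n_raters = nr,
       msr = msr, msc = msc, mse = mse)
}

#' Rater-agreement report
#'
#' Pairwise agreement statistics between raters for each rated item:
#' linearly weighted kappa for ordinal items (integer ratings on 0--4), the
#' agreement ICC for continuous scores (e.g. the 0--12 hand bradykinesia
#' score). Consumes a long-format ratings table.
#'
#' @param ratings Data frame with columns `subject_id`, `rater`, `item`,
#'   `score`.
#' @return Named list per item: either pairwise kappas or an ICC with its
#'   confidence interval.
#' @export
rater_agreement <- function(ratings) {
  need <- c("subject_id", "rater", "item", "score")
  if (!all(need %in% names(ratings)))
    stop("schema error: ratings need columns subject_id, rater, item, score",
         call. = FALSE)
  out <- list()
  for (it in unique(ratings$item)) {
    sub <- ratings[ratings$item == it, ]
    wide <- stats::reshape(sub[c("subject_id", "rater", "score")],
                           idvar = "subject_id", timevar = "rater",
                           direction = "wide")
    m <- as.matrix(wide[, -1, drop = FALSE])
    colnames(m) <- sub("^score\\.", "", colnames(m))
    ordinal <- all(sub$score == round(sub$score)) && max(sub$score) <= 4
    if (ordinal) {
      prs <- utils::combn(colnames(m), 2)
      kap <- apply(prs, 2, function(p) {
        cc <- stats::complete.cases(m[, p])
        weighted_kappa_linear(m[cc, p[1]], m[cc, p[2]], categories = 0:4)
      })
      out[[it]] <- list(type = "weighted_kappa",
                        pairs = data.frame(rater1 = prs[1, ],
                                           rater2 = prs[2, ], kappa = kap))
    } else {
      icc <- icc_agreement(m)
      out[[it]] <- list(type = "icc_agreement", icc = icc$icc,
                        ci95 = icc$ci)
    }
  }
  out
}
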