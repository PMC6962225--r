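#' Bradykinesia measures of one window
#'
#' Band-passes the raw tri-axial window with a fourth-order Butterworth
#' filter at 0.25--3.5 Hz (attenuating tremor), computes the vector
#' magnitude of the filtered signal, and returns the movement amplitude
#' (RMS, g) and smoothness (scaled mean squared jerk, dimensionless) of the
#' window. Only windows with hand movement present and gait absent are
#' eligible; eligibility is enforced by the caller through
#' [eligible_brady_windows()].
#'
#' @param window 3 x n matrix in g (one full window).
#' @param config A [motor_config()].
#' @return List: `rms_g`, `msj`.
#' @export
brady_window_measures <- function(window, config = motor_config()) {
  window <- as_triaxial(window)
  bp <- butterworth_filter(window, config$brady_band_order,
                           config$brady_band_hz, config$fs)
  vm <- vector_magnitude(bp)
  list(rms_g = rms(vm), msj = scaled_mean_squared_jerk(vm, config$fs))
}

#' Eligible bradykinesia windows
#'
#' A window contributes to the amplitude and smoothness measures iff hand
#' movement is present, gait is absent, and the window is not in the
#' exclusion mask (scripted clinical-exam tasks).
#'
#' @param hm Factor/character per window (`HM`/`NHM`).
#' @param gait Logical per window (`NA` treated as no gait).
#' @param excluded Logical per window.
#' @return Logical vector of eligibility.
#' @export
eligible_brady_windows <- function(hm, gait, excluded = NULL) {
  if (is.null(excluded)) excluded <- rep(FALSE, length(hm))
  gait <- !is.na(gait) & gait
  hm == "HM" & !gait & !excluded
}

#' No-movement statistics over a visit
#'
#' The percentage of analyzed time with no hand movement, and the mean
#' duration of no-movement bouts. A bout is a maximal run of consecutive
#' analyzed `NHM` windows; its duration is the run length times the window
#' length. Excluded windows are removed from the analyzed set and break
#' runs, so bouts truncated by an exclusion (or the visit boundary) count at
#' their observed length. With zero bouts the mean is 0 and `has_bouts` is
#' `FALSE`.
#'
#' @param hm Factor/character per window (`HM`/`NHM`), visit order.
#' @param excluded Logical per window (default none).
#' @param config A [motor_config()] (window length).
#' @return List: `pct_time_no_movement`, `mean_no_movement_bout_s`,
#'   `n_bouts`, `has_bouts`.
#' @export
no_movement_statistics <- function(hm, excluded = NULL,
                                   config = motor_config()) {
  if (is.null(excluded)) excluded <- rep(FALSE, length(hm))
  analyzed <- which(!excluded)
  if (!length(analyzed))
    stop("empty-input error: no analyzed windows", call. = FALSE)
  nhm <- hm == "NHM"
  pct <- 100 * sum(nhm[analyzed]) / length(analyzed)
  # runs of consecutive analyzed NHM windows; excluded windows break runs
  run_state <- ifelse(excluded, NA, nhm)
  r <- rle(run_state)
  bout_lengths <- r$lengths[!is.na(r$values) & r$values]
  bouts_s <- bout_lengths * config$window_length_s
  list(pct_time_no_movement = pct,
       mean_no_movement_bout_s = if (length(bouts_s)) mean(bouts_s) else 0,
       n_bouts = length(bouts_s), has_bouts = length(bouts_s) > 0)
}

#' Visit-level bradykinesia summary
#'
#' Aggregates the four bradykinesia measures over a visit: mean RMS
#' amplitude over eligible windows, the configured percentile (default
#' 95th) of scaled mean squared jerk over eligible windows, and the
#' no-movement statistics. With zero eligible windows the amplitude and
#' smoothness are reported as missing (`NA`) with `has_measures = FALSE`,
#' never silently as zero.
#'
#' @param rms_g,msj Numeric per window (`NA` where not eligible/computed).
#' @param hm Factor/character per window (`HM`/`NHM`).
#' @param gait Logical per window.
#' @param excluded Logical per window (scripted-task mask).
#' @param config A [motor_config()].
#' @return List: `amplitude_mean_g`, `smoothness_msj_p95`,
#'   `pct_time_no_movement`, `mean_no_movement_bout_s`, `n_eligible`,
#'   `has_measures`, `has_bouts`.
#' @export
summarize_brady_visit <- function(rms_g, msj, hm, gait, excluded = NULL,
                                  config = motor_config()) {
  if (is.null(excluded)) excluded <- rep(FALSE, length(hm))
  elig <- eligible_brady_windows(hm, gait, excluded)
  nm_excluded <- if (config$pct_no_movement_excludes_gait)
    excluded | (!is.na(gait) & gait) else excluded
  nm <- no_movement_statistics(hm, nm_excluded, config)
  vals_rms <- rms_g[elig]
  vals_msj <- msj[elig]
  has <- any(elig) && any(!is.na(vals_rms))
  list(amplitude_mean_g = if (has) mean(vals_rms, na.rm = TRUE) else NA_real_,
       smoothness_msj_p95 = if (has)
         as.numeric(stats::quantile(vals_msj[!is.na(vals_msj)],
                                    config$brady_jerk_percentile / 100,
                                    type = 7)) else NA_real_,
       pct_time_no_movement = nm$pct_time_no_movement,
       mean_no_movement_bout_s = nm$mean_no_movement_bout_s,
       n_eligible = sum(elig), has_measures = has,
       has_bouts = nm$has_bouts)
}

#' Fit the hand bradykinesia score model
#'
#' Affine least-squares fit of the clinical hand bradykinesia score (0--12,
#' the sum of the finger-tapping, hand-movement and pronation-supination
#' items) on a single sensor predictor, the visit mean movement amplitude
#' (g). The coefficient is expected to be negative: lower movement amplitude
#' accompanies higher bradykinesia. Predictions are clipped to the 0--12
#' score range. Leave-one-subject-out RMSE is reported alongside the fit.
#'
#' @param amplitude_mean_g Visit mean movement amplitude per observation, g.
#' @param score Clinical hand bradykinesia score per observation (0--12).
#' @param subject_id Subject of each observation (for leave-one-subject-out
#'   evaluation; one visit per row is fine).
#' @return Object of class `brady_score_model` with `coef`, `print`,
#'   `predict` and `residuals` methods; fields include `loso_rmse`.
#' @export
fit_score_model <- function(amplitude_mean_g, score, subject_id = NULL) {
  ok <- is.finite(amplitude_mean_g) & is.finite(score)
  x <- amplitude_mean_g[ok]; y <- score[ok]
  if (length(x) < 3)
    stop("data-size error: need at least 3 observations", call. = FALSE)
  if (stats::sd(x) < 1e-12)
    stop("fit error: degenerate predictor variance", call. = FALSE)
  sid <- if (is.null(subject_id)) as.character(seq_along(x))
         else as.character(subject_id)[ok]
  fit <- stats::lm(y ~ x)
  loso_err <- unlist(lapply(unique(sid), function(s) {
    tr <- sid != s
    if (sum(tr) < 3 || stats::sd(x[tr]) < 1e-12) return(NULL)
    f <- stats::lm(y[tr] ~ x[tr])
    pred <- pmin(pmax(stats::coef(f)[1] + stats::coef(f)[2] * x[!tr], 0), 12)
    pred - y[!tr]
  }))
  structure(list(coefficients = stats::setNames(stats::coef(fit),
                                                c("(Intercept)", "amplitude_mean_g")),
                 se = suppressWarnings(summary(fit))$coefficients[, "Std. Error"],
                 fit = fit, loso_rmse = sqrt(mean(loso_err^2)),
                 n = length(x), subjects = unique(sid),
                 data = data.frame(amplitude_mean_g = x, score = y,
                                   subject_id = sid)),
            class = "brady_score_model")
}

#' @export
coef.brady_score_model <- function(object, ...) object$coefficients

#' @export
residuals.brady_score_model <- function(object, ...) stats::residuals(object$fit)

#' @export
print.brady_score_model <- function(x, ...) {
  cat("<brady_score_model> score = a + b * amplitude_mean_g, clipped to [0, 12]\n")
  cat(sprintf("  a = %.3f (se %.3f), b = %.3f (se %.3f)\n",
              x$coefficients[1], x$se[1], x$coefficients[2], x$se[2]))
  cat(sprintf("  n = %d observations, %d subjects; LOSO RMSE = %.3f\n",
              x$n, length(x$subjects), x$loso_rmse))
  invisible(x)
}

#' @export
summary.brady_score_model <- function(object, ...) {
  print(object)
  cat("\nUnderlying least-squares fit:\n")
  print(summary(object$fit))
  invisible(object)
}

#' Predict a hand bradykinesia score
#'
#' @param object A `brady_score_model`.
#' @param amplitude_mean_g Visit mean movement amplitude(s), g. May also be
#'   a visit summary list with an `amplitude_mean_g` field.
#' @param ... Unused.
#' @return Predicted score(s), clipped to `[0, 12]`.
#' @export
predict.brady_score_model <- function(object, amplitude_mean_g, ...) {
  if (is.list(amplitude_mean_g))
    amplitude_mean_g <- amplitude_mean_g$amplitude_mean_g
  b <- object$coefficients
  pmin(pmax(b[[1]] + b[[2]] * amplitude_mean_g, 0), 12)
}
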