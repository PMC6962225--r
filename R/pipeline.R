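#' Run the hierarchical pipeline over one visit
#'
#' Per 3-s window: the hand-movement heuristic decides the context path;
#' windows with hand movement are passed to the gait classifier, and those
#' with hand movement but no gait receive bradykinesia measures; windows at
#' rest (no hand movement) are passed to the tremor classifier and, where
#' tremor is detected, the tremor amplitude. Exactly one context path per
#' window: no window carries both tremor and bradykinesia measures. Visit
#' summaries are assembled from the per-window results. Misclassification
#' at one level propagates down the hierarchy by design; an optional median
#' smoothing of the hand-movement labels (`smooth_labels = TRUE`, off by
#' default) trades isolated-window errors against responsiveness.
#'
#' @param recording An [inertial_recording()].
#' @param gait_model Trained `activity_classifier` (catalog `"gait"`).
#' @param tremor_model Trained `activity_classifier` (catalog `"tremor"`).
#' @param exclusion Optional [interval_set()] of scripted-task intervals
#'   excluded from bradykinesia aggregation.
#' @param config A [motor_config()].
#' @param smooth_labels Apply a 3-window median filter to the hand-movement
#'   labels before the symptom stages (default `FALSE`).
#' @return Object of class `visit_result`: `timeline` (one row per window:
#'   `window_idx`, `t_start_s`, `hand_movement`, `gait`, `tremor`,
#'   `excluded`, `tremor_amp_g`, `brady_rms_g`, `brady_msj`) and `summary`
#'   (a `visit_summary`).
#' @export
run_visit <- function(recording, gait_model, tremor_model, exclusion = NULL,
                      config = motor_config(), smooth_labels = FALSE) {
  if (missing(gait_model) || is.null(gait_model) ||
      missing(tremor_model) || is.null(tremor_model))
    stop("dependency error: trained gait and tremor models are required",
         call. = FALSE)
  if (!identical(gait_model$catalog, "gait"))
    stop("schema error: gait_model was not trained on the gait catalog",
         call. = FALSE)
  if (!identical(tremor_model$catalog, "tremor"))
    stop("schema error: tremor_model was not trained on the tremor catalog",
         call. = FALSE)
  grid <- segment_windows(recording, config)
  n_win <- length(grid$starts)
  mask <- detect_movement_samples(recording$accel, config)
  hm <- classify_movement_windows(mask, grid, config)
  if (smooth_labels && n_win >= 3) {
    v <- as.integer(hm == "HM")
    sm <- stats::filter(v, rep(1, 3), sides = 2)
    hm_new <- ifelse(!is.na(sm) & sm >= 2, "HM", ifelse(!is.na(sm), "NHM", NA))
    hm <- factor(ifelse(is.na(hm_new), as.character(hm), hm_new),
                 levels = c("HM", "NHM"))
  }
  excluded <- if (is.null(exclusion)) rep(FALSE, n_win)
              else labels_from_intervals(grid, exclusion,
                                         unique(exclusion$label),
                                         config$majority_fraction)
  gait <- rep(NA, n_win)
  tremor <- rep(NA, n_win)
  tremor_amp <- rep(NA_real_, n_win)
  brady_rms <- rep(NA_real_, n_win)
  brady_msj <- rep(NA_real_, n_win)

  hm_idx <- which(hm == "HM")
  if (length(hm_idx)) {
    bp <- butterworth_filter(recording$accel, config$gait_band_order,
                             config$gait_band_hz, config$fs)
    gf <- do.call(rbind, lapply(hm_idx, function(k) {
      gait_features_from_bp(window_slice(bp, grid, k), config)
    }))
    gait[hm_idx] <- predict(gait_model, as.data.frame(gf)) == "GAIT"
  }
  rest_idx <- which(hm == "NHM")
  if (length(rest_idx)) {
    ord <- config$tremor_feature_band_order
    tb <- butterworth_filter(recording$accel, ord, config$tremor_band_hz,
                             config$fs)
    nb <- butterworth_filter(recording$accel, ord, config$nontremor_band_hz,
                             config$fs)
    tf <- do.call(rbind, lapply(rest_idx, function(k) {
      tremor_features_from_bp(window_slice(tb, grid, k),
                              window_slice(nb, grid, k), config)
    }))
    tremor[rest_idx] <- predict_tremor(tremor_model, as.data.frame(tf)) == "TREMOR"
    for (k in rest_idx[which(tremor[rest_idx])]) {
      tremor_amp[k] <- tremor_amplitude(window_slice(recording$accel, grid, k),
                                        config)
    }
  }
  elig <- eligible_brady_windows(hm, gait, excluded)
  for (k in which(elig)) {
    m <- brady_window_measures(window_slice(recording$accel, grid, k), config)
    brady_rms[k] <- m$rms_g
    brady_msj[k] <- m$msj
  }
  timeline <- data.frame(window_idx = seq_len(n_win),
                         t_start_s = (grid$starts - 1L) / grid$fs,
                         hand_movement = as.character(hm),
                         gait = as.logical(gait), tremor = as.logical(tremor),
                         excluded = excluded, tremor_amp_g = tremor_amp,
                         brady_rms_g = brady_rms, brady_msj = brady_msj)
  summary <- summarize_timeline(timeline, config)
  summary$subject_id <- recording$subject_id
  summary$cohort <- recording$cohort
  summary$visit <- recording$visit
  structure(list(timeline = timeline, summary = summary, config = config),
            class = "visit_result")
}

#' Assemble a visit summary from a per-window timeline
#'
#' Recomputes the visit summary from a timeline data frame (as emitted by
#' [run_visit()] or read back from the window CSV), so emitted outputs are
#' self-consistent.
#'
#' @param timeline Timeline data frame (see [run_visit()]).
#' @param config A [motor_config()].
#' @return Object of class `visit_summary` (a named list).
#' @export
summarize_timeline <- function(timeline, config = motor_config()) {
  trem <- summarize_tremor_visit(timeline$tremor, timeline$tremor_amp_g,
                                 config)
  brady <- summarize_brady_visit(timeline$brady_rms_g, timeline$brady_msj,
                                 timeline$hand_movement, timeline$gait,
                                 timeline$excluded, config)
  n_win <- nrow(timeline)
  hm <- timeline$hand_movement == "HM"
  gait <- !is.na(timeline$gait) & timeline$gait
  tremor <- !is.na(timeline$tremor) & timeline$tremor
  structure(list(
    tremor_constancy_pct = trem$constancy_pct,
    tremor_amplitude_g = trem$amplitude_g,
    brady_amplitude_g = brady$amplitude_mean_g,
    brady_msj_p95 = brady$smoothness_msj_p95,
    pct_no_movement = brady$pct_time_no_movement,
    mean_no_movement_bout_s = brady$mean_no_movement_bout_s,
    has_brady_measures = brady$has_measures,
    has_bouts = brady$has_bouts,
    n_windows = n_win,
    n_hm = sum(hm), n_gait = sum(gait),
    n_brady = sum(hm & !gait & !timeline$excluded),
    n_rest = sum(!hm), n_tremor = sum(tremor),
    n_excluded = sum(timeline$excluded),
    analyzed_duration_s = n_win * config$window_length_s),
    class = "visit_summary")
}

#' @export
print.visit_summary <- function(x, ...) {
  cat("<visit_summary>")
  if (!is.null(x$subject_id))
    cat(sprintf(" subject %s (%s), visit %d", x$subject_id, x$cohort, x$visit))
  cat("\n")
  cat(sprintf("  windows: %d total | %d hand movement (%d gait, %d brady-eligible) | %d rest (%d tremor) | %d excluded\n",
              x$n_windows, x$n_hm, x$n_gait, x$n_brady, x$n_rest, x$n_tremor,
              x$n_excluded))
  cat(sprintf("  tremor: constancy %.2f%%, amplitude %s g\n",
              x$tremor_constancy_pct,
              if (is.na(x$tremor_amplitude_g)) "NA"
              else sprintf("%.4f", x$tremor_amplitude_g)))
  if (isTRUE(x$has_brady_measures)) {
    cat(sprintf("  bradykinesia: amplitude %.4f g, MSJ p%s %.1f\n",
                x$brady_amplitude_g, "95", x$brady_msj_p95))
  } else {
    cat("  bradykinesia: no eligible windows (measures missing)\n")
  }
  cat(sprintf("  no movement: %.1f%% of analyzed time, mean bout %.1f s\n",
              x$pct_no_movement, x$mean_no_movement_bout_s))
  invisible(x)
}

#' @export
print.visit_result <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' @export
summary.visit_result <- function(object, ...) object$summary

#' Plot a visit timeline
#'
#' Simple base-graphics rendering of the per-window context path and the
#' severity measures along the visit.
#'
#' @param x A `visit_result`.
#' @param ... Passed to `plot`.
#' @export
plot.visit_result <- function(x, ...) {
  tl <- x$timeline
  tmin <- tl$t_start_s / 60
  ctx <- ifelse(tl$hand_movement == "NHM",
                ifelse(!is.na(tl$tremor) & tl$tremor, 2, 1),
                ifelse(!is.na(tl$gait) & tl$gait, 4, 3))
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  plot(tmin, ctx, pch = 15, cex = 0.5, yaxt = "n", ylim = c(0.5, 4.5),
       xlab = "time (min)", ylab = "", main = "context path", ...)
  graphics::axis(2, at = 1:4, las = 1,
                 labels = c("rest", "tremor", "movement", "gait"))
  amp <- ifelse(is.na(tl$tremor_amp_g), tl$brady_rms_g, tl$tremor_amp_g)
  plot(tmin, amp, type = "h", xlab = "time (min)",
       ylab = "amplitude (g)", main = "per-window amplitude")
  invisible(x)
}

#' Write the per-window timeline CSV
#'
#' Fixed schema: `window_idx,t_start_s,hand_movement,gait,tremor,excluded,
#' tremor_amp_g,brady_rms_g,brady_msj`.
#'
#' @param result A `visit_result` (or a timeline data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeline <- function(result, path) {
  tl <- if (inherits(result, "visit_result")) result$timeline else result
  utils::write.csv(tl, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-window timeline CSV
#'
#' @param path Timeline CSV written by [write_timeline()].
#' @return Timeline data frame.
#' @export
read_timeline <- function(path) {
  tl <- utils::read.csv(path)
  need <- c("window_idx", "t_start_s", "hand_movement", "gait", "tremor",
            "excluded", "tremor_amp_g", "brady_rms_g", "brady_msj")
  if (!all(need %in% names(tl)))
    stop("schema error: not a timeline CSV", call. = FALSE)
  tl
}

#' Write a visit summary as JSON
#'
#' Missing measures (no eligible windows) are written as JSON `null`, never
#' as zero.
#'
#' @param result A `visit_result` or `visit_summary`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_visit_summary <- function(result, path) {
  s <- if (inherits(result, "visit_result")) result$summary else result
  jsonlite::write_json(unclass(s), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
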