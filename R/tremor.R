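#' Gyroscope heuristic tremor flag for one window
#'
#' Surrogate for the published gyroscope label-generation heuristic, used to
#' label training windows when video annotation is unavailable. A window is
#' flagged as tremor when all three criteria hold on the tri-axial gyroscope
#' window: (a) the dominant frequency lies in the tremor band (3.5--7.5 Hz),
#' (b) the tremor-band RMS of the vector magnitude of the band-passed signal
#' is at least `gyro_amp_threshold_dps`, and (c) the ratio of tremor-band to
#' movement-band (0.5--3 Hz) power is at least `gyro_ratio_threshold`.
#' Spectral criteria are computed on the sum of the per-axis power spectra,
#' which is invariant under device-frame rotation and avoids the
#' frequency-doubling artifact of rectifying a zero-mean oscillation through
#' the vector magnitude.
#'
#' @param gyro_window 3 x n matrix in deg/s.
#' @param config A [motor_config()] (supplies the thresholds).
#' @return Logical flag.
#' @export
gyro_heuristic_tremor <- function(gyro_window, config = motor_config()) {
  if (is.null(gyro_window)) stop("modality error: gyroscope not present",
                                 call. = FALSE)
  w <- as_triaxial(gyro_window)
  specs <- lapply(1:3, function(a) power_spectrum(w[a, ], config$fs))
  power <- Reduce(`+`, lapply(specs, `[[`, "power"))
  ps <- list(freq = specs[[1]]$freq, power = power)
  domf <- dominant_frequency(ps)
  in_band <- domf >= config$tremor_band_hz[1] & domf <= config$tremor_band_hz[2]
  bp <- butterworth_filter(w, config$tremor_amp_order, config$tremor_band_hz,
                           config$fs)
  amp_ok <- rms(vector_magnitude(bp)) >= config$gyro_amp_threshold_dps
  p_trem <- sum(power[ps$freq >= config$tremor_band_hz[1] &
                        ps$freq <= config$tremor_band_hz[2]])
  p_move <- sum(power[ps$freq >= 0.5 & ps$freq <= 3.0])
  ratio_ok <- p_trem >= config$gyro_ratio_threshold * p_move
  isTRUE(in_band && amp_ok && ratio_ok)
}

#' Per-window heuristic tremor flags for a recording
#'
#' @param recording An [inertial_recording()] with gyroscope channels.
#' @param grid A `window_grid` (defaults to segmenting the recording).
#' @param config A [motor_config()].
#' @return Logical vector, one flag per window.
#' @export
heuristic_tremor_windows <- function(recording, grid = NULL,
                                     config = motor_config()) {
  if (is.null(recording$gyro))
    stop("modality error: gyroscope not present", call. = FALSE)
  if (is.null(grid)) grid <- segment_windows(recording, config)
  vapply(seq_along(grid$starts), function(k) {
    gyro_heuristic_tremor(window_slice(recording$gyro, grid, k), config)
  }, logical(1))
}

#' Build a labelled tremor training set
#'
#' Positive-class windows come from PD recordings where the gyroscope
#' heuristic flags tremor; negative-class windows are all windows of the
#' healthy-control recordings (justified by the absence of tremor in
#' controls). Rows carry the 64-feature tremor catalog; classes are balanced
#' by seeded undersampling before feature selection.
#'
#' @param pd_recordings List of PD [inertial_recording()]s with gyroscope.
#' @param hc_recordings List of HC [inertial_recording()]s.
#' @param config A [motor_config()].
#' @param balance Balance classes before returning (default `TRUE`).
#' @return Data frame: `subject_id`, `window_idx`, `label`
#'   (`TREMOR`/`NOTREMOR`), 64 features.
#' @export
build_tremor_training_set <- function(pd_recordings, hc_recordings,
                                      config = motor_config(),
                                      balance = TRUE) {
  rows <- list()
  for (rec in pd_recordings) {
    grid <- segment_windows(rec, config)
    flags <- heuristic_tremor_windows(rec, grid, config)
    if (!any(flags)) next
    fm <- feature_matrix(rec, grid, config, catalog = "tremor")
    keep <- which(flags)
    rows[[length(rows) + 1L]] <- cbind(subject_id = rec$subject_id,
                                       window_idx = fm$window_idx[keep],
                                       label = "TREMOR",
                                       fm[keep, -1, drop = FALSE])
  }
  if (!length(rows))
    stop("class-coverage error: heuristic found no tremor-positive windows",
         call. = FALSE)
  for (rec in hc_recordings) {
    grid <- segment_windows(rec, config)
    fm <- feature_matrix(rec, grid, config, catalog = "tremor")
    rows[[length(rows) + 1L]] <- cbind(subject_id = rec$subject_id,
                                       window_idx = fm$window_idx,
                                       label = "NOTREMOR",
                                       fm[, -1, drop = FALSE])
  }
  df <- do.call(rbind, rows)
  if (length(unique(df$label)) < 2)
    stop("class-coverage error: training set needs both classes", call. = FALSE)
  df$label <- factor(df$label, levels = c("TREMOR", "NOTREMOR"))
  rownames(df) <- NULL
  if (balance) balance_classes(df, derive_seed(config$rng_seed, 11)) else df
}

#' Train the tremor classifier
#'
#' Recursive feature elimination with cross-validated set-size selection on
#' the 64-feature catalog, then a seeded ten-tree random forest. Shares the
#' machinery of the gait classifier.
#'
#' @param training_set Output of [build_tremor_training_set()].
#' @param config A [motor_config()].
#' @return An `activity_classifier` (catalog `"tremor"`).
#' @export
train_tremor_classifier <- function(training_set, config = motor_config()) {
  bal <- balance_classes(training_set, derive_seed(config$rng_seed, 12))
  selected <- select_features(bal, derive_seed(config$rng_seed, 13),
                              folds = config$rfe_folds)
  train_activity_classifier(bal, selected, config, catalog = "tremor",
                            seed = derive_seed(config$rng_seed, 14))
}

#' Predict tremor on rest windows
#'
#' Tremor is assessed only where the hand is at rest: `rest_features` must
#' contain only windows previously labelled `NHM` by the hand-movement
#' detector. Non-rest windows are never scored.
#'
#' @param classifier An `activity_classifier` with catalog `"tremor"`.
#' @param rest_features Feature rows (64-feature catalog) of rest windows.
#' @return Factor `TREMOR`/`NOTREMOR`, one per row.
#' @export
predict_tremor <- function(classifier, rest_features) {
  if (!identical(classifier$catalog, "tremor"))
    stop("schema error: classifier was not trained on the tremor catalog",
         call. = FALSE)
  predict(classifier, rest_features)
}

#' Tremor amplitude of one window
#'
#' Band-passes the raw tri-axial window in the tremor band (third-order
#' Butterworth, 3.5--7.5 Hz), computes the vector magnitude of the filtered
#' signal, and returns its RMS, in g.
#'
#' @param window 3 x n matrix in g (one full window).
#' @param config A [motor_config()].
#' @return Amplitude in g (scalar, >= 0).
#' @export
tremor_amplitude <- function(window, config = motor_config()) {
  window <- as_triaxial(window)
  npw <- round(config$window_length_s * config$fs)
  if (ncol(window) != npw)
    stop(sprintf("length error: expected a full %d-sample window", npw),
         call. = FALSE)
  bp <- butterworth_filter(window, config$tremor_amp_order,
                           config$tremor_band_hz, config$fs)
  rms(vector_magnitude(bp))
}

#' Visit-level tremor summary
#'
#' Constancy is the percentage of the visit during which resting tremor was
#' detected: `100 * (# tremor windows) / (# all visit windows)` by default
#' (set `constancy_all_windows = FALSE` in the config to use rest windows as
#' the denominator). The visit amplitude is the configured percentile
#' (default 85th, linear interpolation between order statistics) of the
#' per-window amplitudes, by default over tremor-flagged windows only.
#'
#' @param tremor_flag Logical per window: tremor detected (`NA` where tremor
#'   was not assessed, i.e. non-rest windows).
#' @param amplitude_g Numeric per window: tremor amplitude (`NA` where not
#'   computed).
#' @param config A [motor_config()].
#' @return List: `constancy_pct`, `amplitude_g` (`NA` if no tremor
#'   windows), `n_tremor_windows`, `n_windows`.
#' @export
summarize_tremor_visit <- function(tremor_flag, amplitude_g,
                                   config = motor_config()) {
  n <- length(tremor_flag)
  if (n < 1) stop("empty-input error: visit has no windows", call. = FALSE)
  n_trem <- sum(tremor_flag, na.rm = TRUE)
  denom <- if (config$constancy_all_windows) n else sum(!is.na(tremor_flag))
  amps <- if (config$tremor_amp_over_flagged)
    amplitude_g[which(tremor_flag)] else amplitude_g[!is.na(amplitude_g)]
  amps <- amps[!is.na(amps)]
  list(constancy_pct = 100 * n_trem / denom,
       amplitude_g = if (length(amps))
         as.numeric(stats::quantile(amps, config$tremor_amp_percentile / 100,
                                    type = 7)) else NA_real_,
       n_tremor_windows = as.integer(n_trem), n_windows = as.integer(n))
}
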