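#' Per-sample hand-movement detection
#'
#' The heuristic hand-movement detector: vector magnitude of the raw
#' accelerometer stream, sixth-order Butterworth low-pass at 3 Hz (removing
#' tremor-band oscillation), rolling 1-s coefficient of variation, and a
#' strict threshold of 0.01 above which a sample is marked as hand movement.
#'
#' @param accel 3 x N matrix in g (or an [inertial_recording()]).
#' @param config A [motor_config()].
#' @return Object of class `movement_mask`: integer per-sample flags
#'   (1 = hand movement), the rolling coefficient of variation, fs.
#' @export
detect_movement_samples <- function(accel, config = motor_config()) {
  if (inherits(accel, "inertial_recording")) accel <- accel$accel
  accel <- as_triaxial(accel)
  if (ncol(accel) < config$hm_cov_span_s * config$fs)
    stop("recording shorter than the rolling coefficient-of-variation span",
         call. = FALSE)
  vm <- vector_magnitude(accel)
  lp <- butterworth_filter(vm, config$hm_lowpass_order, config$hm_lowpass_hz,
                           config$fs, kind = "lowpass")
  cv <- rolling_cov(lp, config$hm_cov_span_s, config$fs)
  structure(list(flag = as.integer(cv > config$hm_cov_threshold),
                 cv = cv, fs = config$fs),
            class = "movement_mask")
}

#' @export
print.movement_mask <- function(x, ...) {
  cat(sprintf("<movement_mask> %d samples at %g Hz, %.1f%% flagged as hand movement\n",
              length(x$flag), x$fs, 100 * mean(x$flag)))
  invisible(x)
}

#' Per-window hand-movement labels
#'
#' A window is labelled `HM` when strictly more than `majority_fraction`
#' (default 50%) of its samples are flagged as hand movement; a window with
#' exactly half flagged is `NHM`.
#'
#' @param mask A `movement_mask` from [detect_movement_samples()].
#' @param grid A `window_grid` on the same timeline.
#' @param config A [motor_config()].
#' @return Factor with levels `HM`, `NHM`, one label per window.
#' @export
classify_movement_windows <- function(mask, grid, config = motor_config()) {
  frac <- vapply(seq_along(grid$starts), function(k) {
    mean(window_slice(mask$flag, grid, k))
  }, numeric(1))
  factor(ifelse(frac > config$majority_fraction, "HM", "NHM"),
         levels = c("HM", "NHM"))
}
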