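#' Inertial recording container
#'
#' Holds a uniformly sampled tri-axial wrist accelerometer stream (units g),
#' an optional tri-axial gyroscope stream (deg/s), and subject/visit
#' metadata. Time is stored in seconds from recording start on a strictly
#' uniform grid.
#'
#' @param t Time vector, seconds, uniform grid starting anywhere.
#' @param accel 3 x N matrix in g (rows x, y, z).
#' @param gyro Optional 3 x N matrix in deg/s.
#' @param fs Sampling rate in Hz; checked against `t`.
#' @param subject_id Subject identifier.
#' @param cohort `"HC"` or `"PD"`.
#' @param visit Visit number.
#' @return Object of class `inertial_recording`.
#' @export
inertial_recording <- function(t, accel, gyro = NULL, fs = 128,
                               subject_id = "S01", cohort = c("HC", "PD"),
                               visit = 1L) {
  cohort <- match.arg(cohort)
  accel <- as_triaxial(accel)
  n <- ncol(accel)
  if (length(t) != n)
    stop("time vector and accelerometer stream differ in length", call. = FALSE)
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (n > 1) {
    dt <- diff(t)
    if (any(abs(dt - 1 / fs) > 1e-6 / fs))
      stop("non-uniform sampling: time steps deviate from 1/fs", call. = FALSE)
  }
  if (!is.null(gyro)) {
    gyro <- as_triaxial(gyro)
    if (ncol(gyro) != n)
      stop("gyroscope stream length differs from accelerometer", call. = FALSE)
  }
  structure(list(subject_id = subject_id, cohort = cohort,
                 visit = as.integer(visit), t = as.numeric(t),
                 accel = accel, gyro = gyro, fs = fs),
            class = "inertial_recording")
}

#' @export
print.inertial_recording <- function(x, ...) {
  cat(sprintf("<inertial_recording> subject %s (%s), visit %d\n",
              x$subject_id, x$cohort, x$visit))
  cat(sprintf("  %d samples at %g Hz (%.1f s)%s\n", ncol(x$accel), x$fs,
              ncol(x$accel) / x$fs,
              if (is.null(x$gyro)) "" else ", gyroscope present"))
  invisible(x)
}

#' Read a sensor CSV into an inertial recording
#'
#' Canonical on-disk format: header
#' `time_s,ax_g,ay_g,az_g[,gx_dps,gy_dps,gz_dps]`. The sampling rate is
#' inferred from the median time step and checked against the declared `fs`.
#'
#' @param path CSV file path.
#' @param fs Declared sampling rate in Hz.
#' @param subject_id,cohort,visit Metadata attached to the recording.
#' @return An [inertial_recording()].
#' @export
read_recording <- function(path, fs = 128, subject_id = "S01",
                           cohort = c("HC", "PD"), visit = 1L) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time_s", "ax_g", "ay_g", "az_g")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  accel <- t(as.matrix(df[, c("ax_g", "ay_g", "az_g")]))
  if (!all(is.finite(accel)))
    stop("data error: non-finite accelerometer values", call. = FALSE)
  gyro_cols <- c("gx_dps", "gy_dps", "gz_dps")
  gyro <- if (all(gyro_cols %in% names(df))) t(as.matrix(df[, gyro_cols]))
  fs_obs <- 1 / stats::median(diff(df$time_s))
  if (abs(fs_obs - fs) > 1e-3 * fs)
    stop(sprintf("sampling error: observed rate %.3f Hz differs from declared %g Hz",
                 fs_obs, fs), call. = FALSE)
  inertial_recording(df$time_s, accel, gyro, fs = fs, subject_id = subject_id,
                     cohort = match.arg(cohort), visit = visit)
}

#' Write an inertial recording to the canonical sensor CSV
#'
#' @param recording An [inertial_recording()].
#' @param path Output CSV path.
#' @param digits Significant digits written (default preserves round trips
#'   far below sensor resolution).
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, digits = 12) {
  df <- data.frame(time_s = recording$t,
                   ax_g = recording$accel[1, ], ay_g = recording$accel[2, ],
                   az_g = recording$accel[3, ])
  if (!is.null(recording$gyro)) {
    df$gx_dps <- recording$gyro[1, ]
    df$gy_dps <- recording$gyro[2, ]
    df$gz_dps <- recording$gyro[3, ]
  }
  df[] <- lapply(df, function(col) signif(col, digits))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Interval annotations
#'
#' A set of `(start_s, end_s, label)` intervals on a recording's timeline,
#' used for task annotations, ground-truth states and exclusion masks.
#'
#' @param start_s,end_s Interval bounds in seconds, `start_s < end_s`.
#' @param label Character labels.
#' @param duration_s Optional recording duration; intervals must fit inside.
#' @return Object of class `interval_set` (a data frame).
#' @export
interval_set <- function(start_s, end_s, label, duration_s = NULL) {
  if (any(start_s >= end_s))
    stop("intervals must satisfy start_s < end_s", call. = FALSE)
  if (!is.null(duration_s) && (any(start_s < 0) || any(end_s > duration_s + 1e-9)))
    stop("intervals fall outside the recording duration", call. = FALSE)
  structure(data.frame(start_s = start_s, end_s = end_s,
                       label = as.character(label),
                       stringsAsFactors = FALSE),
            class = c("interval_set", "data.frame"))
}

#' @rdname interval_set
#' @param path Annotation CSV with header `start_s,end_s,label`.
#' @export
read_intervals <- function(path, duration_s = NULL) {
  df <- utils::read.csv(path)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df)))
    stop("schema error: annotation CSV needs columns start_s,end_s,label",
         call. = FALSE)
  interval_set(df$start_s, df$end_s, df$label, duration_s = duration_s)
}

#' @rdname interval_set
#' @param intervals An `interval_set`.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.csv(as.data.frame(unclass(intervals))[c("start_s", "end_s", "label")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Segment a recording into non-overlapping windows
#'
#' Divides the recording into contiguous, disjoint windows of
#' `window_length_s` seconds (384 samples at 128 Hz with the default 3-s
#' window); the trailing partial window is dropped, not padded, so visit
#' aggregates are duration-weighted over full windows only.
#'
#' @param recording An [inertial_recording()], or an integer sample count.
#' @param config A [motor_config()].
#' @return Object of class `window_grid`: start sample indices (1-based,
#'   half-open ranges `[start, start + n_per_window)`), `n_per_window`, fs.
#' @export
segment_windows <- function(recording, config = motor_config()) {
  n <- if (inherits(recording, "inertial_recording")) ncol(recording$accel)
       else as.integer(recording)
  npw <- as.integer(round(config$window_length_s * config$fs))
  n_win <- n %/% npw
  if (n_win < 1)
    stop(sprintf("recording too short: %d samples is less than one %d-sample window",
                 n, npw), call. = FALSE)
  structure(list(starts = seq.int(1L, by = npw, length.out = n_win),
                 n_per_window = npw,
                 window_length_s = config$window_length_s,
                 fs = config$fs),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat(sprintf("<window_grid> %d windows of %d samples (%g s at %g Hz)\n",
              length(x$starts), x$n_per_window, x$window_length_s, x$fs))
  invisible(x)
}

window_slice <- function(mat, grid, k) {
  idx <- seq.int(grid$starts[k], length.out = grid$n_per_window)
  if (is.matrix(mat)) mat[, idx, drop = FALSE] else mat[idx]
}

#' Label windows from interval annotations
#'
#' A window is positive when its overlap with positively labelled intervals
#' strictly exceeds `majority_fraction` of the window length ("more than
#' 50%"): a window covered for exactly half its duration is negative.
#'
#' @param grid A `window_grid`.
#' @param intervals An [interval_set()].
#' @param positive_label Label(s) counted as positive.
#' @param majority_fraction Strict exceedance threshold (fraction of window).
#' @return Logical vector, one value per window.
#' @export
labels_from_intervals <- function(grid, intervals, positive_label,
                                  majority_fraction = 0.5) {
  pos <- intervals[intervals$label %in% positive_label, , drop = FALSE]
  pos <- merge_intervals(pos)
  t0 <- (grid$starts - 1L) / grid$fs
  t1 <- t0 + grid$window_length_s
  overlap <- numeric(length(t0))
  for (i in seq_len(nrow(pos))) {
    overlap <- overlap + pmax(0, pmin(t1, pos$end_s[i]) - pmax(t0, pos$start_s[i]))
  }
  overlap > majority_fraction * grid$window_length_s + 1e-12
}

# union of possibly overlapping intervals, so coverage is never double-counted
merge_intervals <- function(df) {
  if (nrow(df) < 2) return(df)
  df <- df[order(df$start_s), , drop = FALSE]
  out_start <- df$start_s[1]
  out_end <- df$end_s[1]
  starts <- ends <- numeric(0)
  for (i in seq_len(nrow(df))[-1]) {
    if (df$start_s[i] <= out_end) {
      out_end <- max(out_end, df$end_s[i])
    } else {
      starts <- c(starts, out_start); ends <- c(ends, out_end)
      out_start <- df$start_s[i]; out_end <- df$end_s[i]
    }
  }
  data.frame(start_s = c(starts, out_start), end_s = c(ends, out_end),
             label = df$label[1], stringsAsFactors = FALSE)
}
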