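#' Build a labelled gait training set
#'
#' Extracts the 47-feature gait catalog from every full window of each
#' recording and labels windows from task interval annotations: windows
#' majority-covered by a positive (gait) task label become `GAIT`, windows
#' majority-covered by an excluded task (mixed tasks containing sporadic
#' gait, e.g. carrying tasks) are omitted entirely, and remaining windows
#' become `NOGAIT`.
#'
#' @param recordings List of [inertial_recording()] objects.
#' @param intervals List of [interval_set()] task annotations, one per
#'   recording.
#' @param positive_labels Interval labels treated as gait.
#' @param exclude_labels Interval labels whose windows are omitted.
#' @param config A [motor_config()].
#' @return Data frame: `subject_id`, `window_idx`, `label` (factor
#'   `GAIT`/`NOGAIT`), and the 47 gait features.
#' @export
build_gait_training_set <- function(recordings, intervals,
                                    positive_labels = "GAIT",
                                    exclude_labels = character(),
                                    config = motor_config()) {
  stopifnot(length(recordings) == length(intervals))
  out <- vector("list", length(recordings))
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    grid <- segment_windows(rec, config)
    pos <- labels_from_intervals(grid, intervals[[i]], positive_labels,
                                 config$majority_fraction)
    excl <- if (length(exclude_labels))
      labels_from_intervals(grid, intervals[[i]], exclude_labels,
                            config$majority_fraction)
    else rep(FALSE, length(pos))
    keep <- which(!excl)
    if (!length(keep)) next
    fm <- feature_matrix(rec, grid, config, catalog = "gait")
    out[[i]] <- cbind(subject_id = rec$subject_id,
                      window_idx = fm$window_idx[keep],
                      label = ifelse(pos[keep], "GAIT", "NOGAIT"),
                      fm[keep, -1, drop = FALSE])
  }
  df <- do.call(rbind, out)
  if (is.null(df) || length(unique(df$label)) < 2)
    stop("class-coverage error: training set needs both gait and non-gait windows",
         call. = FALSE)
  df$label <- factor(df$label, levels = c("GAIT", "NOGAIT"))
  rownames(df) <- NULL
  df
}

#' Train the gait classifier
#'
#' Balances classes by seeded undersampling, runs recursive feature
#' elimination with cross-validated set-size selection, and fits the seeded
#' ten-tree random forest.
#'
#' @param training_set Output of [build_gait_training_set()].
#' @param config A [motor_config()].
#' @return An `activity_classifier` (catalog `"gait"`).
#' @export
train_gait_classifier <- function(training_set, config = motor_config()) {
  bal <- balance_classes(training_set, derive_seed(config$rng_seed, 1))
  selected <- select_features(bal, derive_seed(config$rng_seed, 2),
                              folds = config$rfe_folds)
  train_activity_classifier(bal, selected, config, catalog = "gait",
                            seed = derive_seed(config$rng_seed, 3))
}
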