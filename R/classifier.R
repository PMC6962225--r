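#' Balance classes by seeded undersampling
#'
#' Randomly undersamples the majority class, without replacement, to the
#' minority-class count. Deterministic for a given seed; an already balanced
#' input is returned unchanged (up to row order).
#'
#' @param data Data frame with a `label` column (factor or character, two
#'   classes) plus feature columns.
#' @param seed Integer seed.
#' @return Data frame with equal class counts.
#' @export
balance_classes <- function(data, seed) {
  tab <- table(as.character(data$label))
  if (length(tab) < 2)
    stop("class-coverage error: both classes must be present", call. = FALSE)
  n_min <- min(tab)
  set.seed(seed)
  keep <- unlist(lapply(names(tab), function(cl) {
    idx <- which(as.character(data$label) == cl)
    if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
  }))
  data[sort(keep), , drop = FALSE]
}

feature_columns <- function(data) {
  setdiff(names(data), c("subject_id", "window_idx", "label"))
}

# deterministic stratified fold assignment; when subject identities are
# available and plentiful, folds group whole subjects so the inner CV
# rewards feature sets that generalize across subjects (and hence device
# orientations) rather than within-subject shortcuts
stratified_folds <- function(label, k, seed, subject = NULL) {
  set.seed(seed)
  if (!is.null(subject)) {
    subj <- unique(as.character(subject))
    if (length(subj) >= k) {
      sf <- sample(rep_len(seq_len(k), length(subj)))
      fold <- sf[match(as.character(subject), subj)]
      # every fold must see both classes in its training part
      ok <- all(vapply(seq_len(k), function(f)
        length(unique(as.character(label)[fold != f])) == 2, logical(1)))
      if (ok) return(fold)
    }
  }
  fold <- integer(length(label))
  for (cl in unique(as.character(label))) {
    idx <- which(as.character(label) == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Recursive feature elimination with cross-validated set-size selection
#'
#' Starting from the full catalog, repeatedly records the stratified
#' k-fold cross-validated accuracy of a decision-tree classifier on the
#' current feature set, then drops the least important feature (by the
#' tree's variable importance; features unused by the tree count as zero).
#' The retained set is the one with the highest cross-validated accuracy;
#' exact ties go to the larger set, so a feature is discarded only when the
#' cross-validation shows no cost to discarding it and pruning below the
#' accuracy maximum never happens. Folds group whole subjects whenever
#' enough subjects are available, so retained sets must generalize across
#' subjects (and device orientations), not merely within them.
#'
#' @param data Balanced data frame with `label` and feature columns.
#' @param seed Integer seed (controls fold assignment).
#' @param folds Number of cross-validation folds.
#' @return Character vector of selected feature names (length >= 1).
#' @export
select_features <- function(data, seed, folds = 5) {
  feats <- feature_columns(data)
  label <- factor(data$label)
  if (nlevels(label) < 2)
    stop("class-coverage error: both classes must be present", call. = FALSE)
  if (nrow(data) < folds)
    stop("data-size error: fewer rows than cross-validation folds", call. = FALSE)
  fold <- stratified_folds(label, folds, seed, subject = data$subject_id)
  current <- feats
  trace_sets <- list()
  trace_acc <- numeric(0)
  while (length(current) >= 1) {
    acc <- mean(vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- rpart_fit(data[tr, current, drop = FALSE], label[tr])
      pred <- rpart_predict(fit, data[!tr, current, drop = FALSE])
      mean(pred == label[!tr])
    }, numeric(1)))
    trace_sets[[length(trace_sets) + 1L]] <- current
    trace_acc <- c(trace_acc, acc)
    if (length(current) == 1) break
    fit_all <- rpart_fit(data[, current, drop = FALSE], label)
    imp <- fit_all$variable.importance
    scores <- stats::setNames(numeric(length(current)), current)
    if (!is.null(imp)) scores[names(imp)] <- imp
    # drop the least important; ties broken toward the later column
    drop_i <- max(which(scores == min(scores)))
    current <- current[-drop_i]
  }
  # highest CV accuracy; ties -> largest set (sets shrink along the trace)
  sizes <- lengths(trace_sets)
  best <- which(trace_acc >= max(trace_acc) - 1e-12)
  trace_sets[[best[which.max(sizes[best])]]]
}

rpart_fit <- function(x, y) {
  df <- cbind(.label = y, x)
  rpart::rpart(.label ~ ., data = df, method = "class",
               control = rpart::rpart.control(xval = 0, cp = 0.01))
}

rpart_predict <- function(fit, x) {
  cls <- predict(fit, newdata = x, type = "class")
  factor(as.character(cls), levels = attr(fit, "ylevels"))
}

#' Train an activity (gait or tremor) window classifier
#'
#' Fits a seeded random forest (ten trees by default) on the selected
#' features. The returned object carries the selected feature names, the
#' catalog identity and training metadata, and predicts through
#' [predict.activity_classifier()].
#'
#' @param data Balanced data frame with `label` and feature columns.
#' @param selected Feature names to train on (subset of the catalog);
#'   default selects via [select_features()].
#' @param config A [motor_config()].
#' @param catalog Catalog identifier stored in metadata (`"gait"` or
#'   `"tremor"`).
#' @param seed Integer seed for the forest (default derived from the config
#'   base seed).
#' @return Object of class `activity_classifier`.
#' @export
train_activity_classifier <- function(data, selected = NULL,
                                      config = motor_config(),
                                      catalog = "gait", seed = NULL) {
  if (is.null(seed)) seed <- derive_seed(config$rng_seed, 3)
  if (is.null(selected))
    selected <- select_features(data, derive_seed(config$rng_seed, 2),
                                folds = config$rfe_folds)
  missing_cols <- setdiff(selected, names(data))
  if (length(missing_cols))
    stop("schema error: unseen feature name(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  y <- factor(data$label)
  set.seed(seed)
  forest <- randomForest::randomForest(x = data[, selected, drop = FALSE],
                                       y = y, ntree = config$n_estimators)
  structure(list(forest = forest, features = selected, catalog = catalog,
                 metadata = list(seed = seed,
                                 n_estimators = config$n_estimators,
                                 class_counts = as.list(table(y)),
                                 subjects = unique(as.character(data$subject_id)))),
            class = "activity_classifier")
}

#' @export
print.activity_classifier <- function(x, ...) {
  cat(sprintf("<activity_classifier> catalog: %s, %d trees, %d/%d features\n",
              x$catalog, x$metadata$n_estimators, length(x$features),
              length(if (x$catalog == "gait") gait_feature_names()
                     else tremor_feature_names())))
  cnt <- unlist(x$metadata$class_counts)
  cat("  training windows:", paste(sprintf("%s=%d", names(cnt), cnt),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Predict window labels with a trained classifier
#'
#' @param object An `activity_classifier`.
#' @param newdata Data frame containing at least the selected feature
#'   columns; zero rows give zero predictions.
#' @param ... Unused.
#' @return Factor of predicted labels, one per row of `newdata`.
#' @export
predict.activity_classifier <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols))
    stop("schema error: feature catalog mismatch, missing ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  lev <- levels(object$forest$y)
  if (nrow(newdata) == 0) return(factor(character(0), levels = lev))
  predict(object$forest, newdata = newdata[, object$features, drop = FALSE])
}

# the whole per-fold training pipeline: the held-out subject's rows are
# removed before balancing, selection and training, so they cannot leak
loso_fold_model <- function(data, held, fold_index, config, select = TRUE) {
  train_df <- data[data$subject_id != held, , drop = FALSE]
  bal <- balance_classes(train_df,
                         derive_seed(config$rng_seed, 100 + fold_index))
  selected <- if (select)
    select_features(bal, derive_seed(config$rng_seed, 200 + fold_index),
                    folds = config$rfe_folds)
  else feature_columns(data)
  train_activity_classifier(bal, selected, config,
                            seed = derive_seed(config$rng_seed,
                                               300 + fold_index))
}

classification_metrics <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  classes <- sort(unique(c(truth, pred)))
  per_class <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(support = sum(truth == cl), precision = prec, recall = rec, f1 = f1)
  })
  m <- do.call(rbind, per_class)
  wts <- m[, "support"] / sum(m[, "support"])
  neg_truth <- truth != positive
  pos_truth <- truth == positive
  list(accuracy = mean(truth == pred),
       precision_weighted = sum(wts * m[, "precision"]),
       recall_weighted = sum(wts * m[, "recall"]),
       f1_weighted = sum(wts * m[, "f1"]),
       false_positive_rate = if (any(neg_truth))
         mean(pred[neg_truth] == positive) else NA_real_,
       false_negative_rate = if (any(pos_truth))
         mean(pred[pos_truth] != positive) else NA_real_)
}

#' Leave-one-subject-out evaluation
#'
#' For each subject in turn, the full training pipeline -- class balancing,
#' recursive feature elimination, forest training -- is re-run on the
#' remaining subjects only (so the held-out subject can never leak into
#' balancing, selection or training) and the held-out subject's windows are
#' predicted. Metrics are pooled over all held-out predictions.
#'
#' @param data Labelled feature data frame with `subject_id`, `label` and
#'   feature columns (from [build_gait_training_set()] or
#'   [build_tremor_training_set()]).
#' @param config A [motor_config()].
#' @param positive Label of the positive class (for FPR/FNR).
#' @param select If `FALSE`, skip feature elimination inside folds (all
#'   catalog features used); cuts runtime for smoke tests.
#' @return Object of class `loso_report`: pooled metrics, per-subject
#'   confusion counts, predictions.
#' @export
loso_evaluate <- function(data, config = motor_config(), positive,
                          select = TRUE) {
  subjects <- unique(as.character(data$subject_id))
  if (length(subjects) < 2)
    stop("data-size error: leave-one-subject-out needs >= 2 subjects",
         call. = FALSE)
  lev <- levels(factor(data$label))
  preds <- truths <- character(0)
  subj_of <- character(0)
  for (i in seq_along(subjects)) {
    held <- subjects[i]
    test_df <- data[data$subject_id == held, , drop = FALSE]
    clf <- loso_fold_model(data, held, i, config, select)
    p <- predict(clf, test_df)
    preds <- c(preds, as.character(p))
    truths <- c(truths, as.character(test_df$label))
    subj_of <- c(subj_of, rep(held, nrow(test_df)))
  }
  metrics <- classification_metrics(truths, preds, positive)
  confusion <- table(subject = subj_of, truth = truths, predicted = preds)
  structure(c(metrics,
              list(confusion = confusion, n_windows = length(truths),
                   subjects = subjects, positive = positive,
                   truth = truths, predicted = preds, subject = subj_of)),
            class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  cat(sprintf("<loso_report> %d subjects, %d windows (positive class: %s)\n",
              length(x$subjects), x$n_windows, x$positive))
  cat(sprintf("  accuracy %.3f | weighted precision %.3f recall %.3f F1 %.3f\n",
              x$accuracy, x$precision_weighted, x$recall_weighted,
              x$f1_weighted))
  cat(sprintf("  false-positive rate %.3f | false-negative rate %.3f\n",
              x$false_positive_rate, x$false_negative_rate))
  invisible(x)
}
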