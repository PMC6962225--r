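# shared fixtures; heavier artifacts (trained models) are built once per
# test run and cached in this environment
.fixtures <- new.env(parent = emptyenv())

test_config <- function(...) motor_config(...)

# one 3-s window: gravity along z plus an oscillation along `u`
osc_window <- function(freq_hz, amp_g, u = c(1, 0, 0), fs = 128,
                       n = 384, noise_sd = 0, gravity = c(0, 0, 1),
                       phase = 0) {
  t <- (seq_len(n) - 1) / fs
  u <- u / sqrt(sum(u^2))
  w <- gravity %o% rep(1, n) + u %o% (amp_g * sin(2 * pi * freq_hz * t + phase))
  if (noise_sd > 0) w <- w + matrix(rnorm(3 * n, sd = noise_sd), 3, n)
  w
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

# trained gait + tremor models on a fixed simulated cohort (built once)
fixture_models <- function() {
  if (!is.null(.fixtures$models)) return(.fixtures$models)
  cfg <- test_config()
  cohort <- simulate_cohort(5, 10, seed = 11, config = cfg, visit_s = 180)
  recs <- lapply(cohort, `[[`, "recording")
  is_pd <- vapply(recs, function(r) r$cohort == "PD", logical(1))
  gait_model <- train_gait_classifier(
    build_gait_training_set(recs, lapply(cohort, function(s) s$truth$intervals),
                            config = cfg),
    cfg)
  tremor_model <- train_tremor_classifier(
    build_tremor_training_set(recs[is_pd], recs[!is_pd], cfg), cfg)
  .fixtures$models <- list(gait = gait_model, tremor = tremor_model,
                           config = cfg)
  .fixtures$models
}

# small labelled feature set where the class signal is split across two
# planted features (each informative on a different half of the rows, so
# both are needed for full separation) amid pure-noise features
planted_feature_set <- function(n_per_class = 40, n_noise = 10, seed = 5) {
  set.seed(seed)
  label <- rep(c("A", "B"), each = n_per_class)
  n <- 2 * n_per_class
  df <- data.frame(subject_id = rep(sprintf("S%02d", 1:8), length.out = n),
                   window_idx = seq_len(n), label = label)
  first_half <- (seq_len(n) %% n_per_class) < n_per_class / 2
  cls <- ifelse(label == "A", 1, -1)
  df$sig1 <- ifelse(first_half, 2 * cls, 0) + rnorm(n, sd = 0.2)
  df$sig2 <- ifelse(first_half, 0, -2 * cls) + rnorm(n, sd = 0.2)
  for (j in seq_len(n_noise)) df[[paste0("noise", j)]] <- rnorm(n)
  df
}
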