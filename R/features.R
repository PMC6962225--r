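#' Hann-tapered periodogram of one window
#'
#' Power spectral density at the native frequency resolution `fs / n`
#' (1/3 Hz for a 3-s window): the signal is demeaned, multiplied by a Hann
#' taper, and the one-sided periodogram is scaled so that the total power
#' (`sum(power) * df`) equals the taper-corrected variance of the window
#' (Parseval). No zero-padding.
#'
#' @param x Numeric vector (one full window).
#' @param fs Sampling rate in Hz.
#' @return List with `freq` (Hz, from 0 to fs/2) and `power` (units^2/Hz).
#' @export
power_spectrum <- function(x, fs) {
  n <- length(x)
  if (n < 8) stop("window too short for a periodogram", call. = FALSE)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / n))  # Hann
  xw <- (x - mean(x)) * w
  X <- stats::fft(xw)
  n_keep <- n %/% 2 + 1L
  p <- Mod(X[seq_len(n_keep)])^2 / (fs * sum(w^2))
  # double interior bins to fold negative frequencies into the one-sided PSD
  interior <- 2:(n_keep - if (n %% 2 == 0) 1L else 0L)
  p[interior] <- 2 * p[interior]
  list(freq = (seq_len(n_keep) - 1L) * fs / n, power = p)
}

dominant_frequency <- function(ps) {
  nz <- ps$freq > 0
  ps$freq[nz][which.max(ps$power[nz])]
}

power_at_dominant <- function(ps) {
  nz <- ps$freq > 0
  max(ps$power[nz])
}

band_relative_power <- function(ps, band) {
  tot <- sum(ps$power)
  if (tot <= 0) return(0)
  sum(ps$power[ps$freq >= band[1] & ps$freq <= band[2]]) / tot
}

# normalized Shannon entropy of the power spectrum, in [0, 1]
spectral_entropy <- function(ps) {
  p <- ps$power
  tot <- sum(p)
  if (tot <= 0) return(1)
  p <- p[p > 0] / tot
  -sum(p * log(p)) / log(length(ps$power))
}

zero_crossing_rate <- function(x, fs) {
  if (length(x) < 2) return(0)
  sum(x[-length(x)] * x[-1] < 0) / (length(x) / fs)
}

#' Feature catalog names
#'
#' The gait catalog has 47 features: 11 statistics for each of 4 processed
#' signals (the three 0.25--3.0 Hz band-passed axes and their first
#' principal component), plus 3 cross-signal features (mean pairwise
#' inter-axis correlation, the autocorrelation peak of the PCA signal in the
#' 0.3--1.0 s step-time lag range, and the cadence implied by that lag).
#' The tremor catalog has 64 features: 8 statistics for each of 8 processed
#' signals (three axes plus PCA in each of the non-tremor 0.25--3.0 Hz and
#' tremor 3.5--7.5 Hz bands). Catalogs are fixed name registries so that an
#' alternative feature list can be swapped in without code changes.
#'
#' @return Character vector of feature names (length 47 or 64).
#' @export
gait_feature_names <- function() {
  sigs <- c("bpx", "bpy", "bpz", "pca")
  stats <- c("mean", "sd", "cov", "rms", "range", "iqr", "skewness",
             "kurtosis", "domfreq_hz", "relpower_gait", "spec_entropy")
  c(as.vector(t(outer(sigs, stats, paste, sep = "_"))),
    "axis_corr_mean", "step_acf_peak", "cadence_spm")
}

#' @rdname gait_feature_names
#' @export
tremor_feature_names <- function() {
  sigs <- c("tb_x", "tb_y", "tb_z", "tb_pca",
            "nb_x", "nb_y", "nb_z", "nb_pca")
  stats <- c("rms", "var", "range", "zcr", "domfreq_hz", "dompower",
             "relpower_tremor", "spec_entropy")
  as.vector(t(outer(sigs, stats, paste, sep = "_")))
}

gait_signal_stats <- function(s, fs, eps = 1e-6) {
  ps <- power_spectrum(s, fs)
  mu <- mean(s)
  c(mean = mu,
    sd = stats::sd(s),
    cov = stats::sd(s) / max(abs(mu), eps),
    rms = rms(s),
    range = diff(range(s)),
    iqr = stats::IQR(s),
    skewness = e1071::skewness(s, type = 2),
    kurtosis = e1071::kurtosis(s, type = 2),
    domfreq_hz = dominant_frequency(ps),
    relpower_gait = band_relative_power(ps, c(0.5, 3.0)),
    spec_entropy = spectral_entropy(ps))
}

tremor_signal_stats <- function(s, fs, tremor_band) {
  ps <- power_spectrum(s, fs)
  c(rms = rms(s),
    var = stats::var(s),
    range = diff(range(s)),
    zcr = zero_crossing_rate(s - mean(s), fs),
    domfreq_hz = dominant_frequency(ps),
    dompower = power_at_dominant(ps),
    relpower_tremor = band_relative_power(ps, tremor_band),
    spec_entropy = spectral_entropy(ps))
}

#' Gait features of one window
#'
#' Band-passes the tri-axial window in the gait band (first-order
#' Butterworth, 0.25--3.0 Hz by default), derives the orientation-free first
#' principal component, and computes the 47-feature gait catalog (see
#' [gait_feature_names()]).
#'
#' @param window 3 x n matrix in g (one full window).
#' @param config A [motor_config()].
#' @return Named numeric vector of length 47, all finite.
#' @export
gait_features <- function(window, config = motor_config()) {
  window <- as_triaxial(window)
  bp <- butterworth_filter(window, config$gait_band_order,
                           config$gait_band_hz, config$fs)
  gait_features_from_bp(bp, config)
}

# features from an already band-passed window; the recording-level paths
# filter the continuous stream once before segmenting, which keeps the slow
# 0.25 Hz band edge free of per-window settling artifacts
gait_features_from_bp <- function(bp, config) {
  pca <- pca_first_component(bp)
  sig_list <- list(bp[1, ], bp[2, ], bp[3, ], pca)
  vals <- unlist(lapply(sig_list, gait_signal_stats, fs = config$fs),
                 use.names = FALSE)

  cors <- stats::cor(t(bp))[upper.tri(diag(3))]
  cors[!is.finite(cors)] <- 0
  acf_res <- step_autocorrelation(pca, config$fs)
  out <- c(vals, mean(cors), acf_res["peak"], acf_res["cadence_spm"])
  names(out) <- gait_feature_names()
  if (!all(is.finite(out))) stop("non-finite gait feature", call. = FALSE)
  out
}

# autocorrelation peak of the PCA signal constrained to gait-periodicity
# lags (0.3-1.5 s: step times at normative cadence and, at the wrist where
# arm swing dominates, stride times) and the cadence it implies, steps/min;
# lags beyond 0.75 s are read as stride (two-step) periods
step_autocorrelation <- function(s, fs, lag_range_s = c(0.3, 1.5)) {
  n <- length(s)
  max_lag <- min(as.integer(ceiling(lag_range_s[2] * fs)), n - 1L)
  ac <- stats::acf(s, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1L
  # undo the n-divisor (triangular) bias so long lags are comparable on
  # short windows; clamp to [-1, 1]
  ac <- pmin(pmax(ac * n / (n - lags), -1), 1)
  keep <- lags >= lag_range_s[1] * fs & lags <= lag_range_s[2] * fs
  if (!any(keep)) return(c(peak = 0, cadence_spm = 0))
  ac_k <- ac[keep]
  lag_k <- lags[keep]
  # prefer true local maxima of the autocorrelation (the step-time peak);
  # the range edge only wins when no interior peak exists
  interior <- which(lags > 1 & lags < max(lags))
  loc <- interior[ac[interior] > ac[interior - 1L] &
                    ac[interior] >= ac[interior + 1L]]
  loc <- loc[lags[loc] %in% lag_k]
  best_lag <- if (length(loc)) lags[loc[which.max(ac[loc])]]
              else lag_k[which.max(ac_k)]
  steps_per_lag <- if (best_lag / fs > 0.75) 2 else 1
  c(peak = ac[best_lag + 1L],
    cadence_spm = steps_per_lag * 60 * fs / best_lag)
}

#' Tremor features of one window
#'
#' Band-passes the tri-axial window in the non-tremor (0.25--3.0 Hz) and
#' tremor (3.5--7.5 Hz) bands with first-order Butterworth filters, adds the
#' first principal component of each band, and computes the 64-feature
#' tremor catalog (see [tremor_feature_names()]).
#'
#' @inheritParams gait_features
#' @return Named numeric vector of length 64, all finite.
#' @export
tremor_features <- function(window, config = motor_config()) {
  window <- as_triaxial(window)
  ord <- config$tremor_feature_band_order
  tb <- butterworth_filter(window, ord, config$tremor_band_hz, config$fs)
  nb <- butterworth_filter(window, ord, config$nontremor_band_hz, config$fs)
  tremor_features_from_bp(tb, nb, config)
}

tremor_features_from_bp <- function(tb, nb, config) {
  sig_list <- list(tb[1, ], tb[2, ], tb[3, ], pca_first_component(tb),
                   nb[1, ], nb[2, ], nb[3, ], pca_first_component(nb))
  vals <- unlist(lapply(sig_list, tremor_signal_stats, fs = config$fs,
                        tremor_band = config$tremor_band_hz),
                 use.names = FALSE)
  names(vals) <- tremor_feature_names()
  if (!all(is.finite(vals))) stop("non-finite tremor feature", call. = FALSE)
  vals
}

#' Per-window feature matrix of a recording
#'
#' Applies [gait_features()] or [tremor_features()] to every window of the
#' grid and returns the rows as a data frame with a `window_idx` column.
#'
#' @param recording An [inertial_recording()].
#' @param grid A `window_grid` (defaults to segmenting the recording).
#' @param config A [motor_config()].
#' @param catalog `"gait"` or `"tremor"`.
#' @return Data frame: `window_idx` plus one column per catalog feature.
#' @export
feature_matrix <- function(recording, grid = NULL, config = motor_config(),
                           catalog = c("gait", "tremor")) {
  catalog <- match.arg(catalog)
  if (is.null(grid)) grid <- segment_windows(recording, config)
  rows <- if (catalog == "gait") {
    bp <- butterworth_filter(recording$accel, config$gait_band_order,
                             config$gait_band_hz, config$fs)
    lapply(seq_along(grid$starts), function(k) {
      gait_features_from_bp(window_slice(bp, grid, k), config)
    })
  } else {
    ord <- config$tremor_feature_band_order
    tb <- butterworth_filter(recording$accel, ord, config$tremor_band_hz,
                             config$fs)
    nb <- butterworth_filter(recording$accel, ord, config$nontremor_band_hz,
                             config$fs)
    lapply(seq_along(grid$starts), function(k) {
      tremor_features_from_bp(window_slice(tb, grid, k),
                              window_slice(nb, grid, k), config)
    })
  }
  out <- as.data.frame(do.call(rbind, rows))
  cbind(window_idx = seq_along(grid$starts), out)
}
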