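#' Vector magnitude of a tri-axial signal
#'
#' Elementwise Euclidean norm `sqrt(x^2 + y^2 + z^2)`, removing dependence on
#' device orientation.
#'
#' @param triaxial 3 x N numeric matrix (rows = axes) in g.
#' @return Numeric vector of length N, in g.
#' @export
vector_magnitude <- function(triaxial) {
  triaxial <- as_triaxial(triaxial)
  sqrt(colSums(triaxial^2))
}

as_triaxial <- function(x) {
  if (is.data.frame(x)) x <- t(as.matrix(x))
  if (!is.matrix(x)) stop("expected a 3 x N matrix", call. = FALSE)
  if (nrow(x) != 3 && ncol(x) == 3) x <- t(x)
  if (nrow(x) != 3) stop("expected a 3 x N matrix", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite samples in tri-axial signal",
                               call. = FALSE)
  dimnames(x) <- NULL
  x
}

#' Zero-phase Butterworth filter
#'
#' Designs a Butterworth IIR filter and applies it forward and backward
#' (zero phase). Offline processing makes zero-phase application the natural
#' choice: per-window phase distortion would bias downstream RMS and jerk
#' measures. Note the doubled effective order and squared magnitude response
#' of the forward--backward pass. Edges are handled by odd reflection
#' padding of length `3 * (order for lowpass; 2 * order for bandpass)`
#' filter coefficients, which keeps 3-s windows usable at the configured
#' orders.
#'
#' @param x Numeric vector, or 3 x N matrix filtered row-wise.
#' @param order Filter order (of the one-way design).
#' @param cutoff Scalar cutoff in Hz (lowpass) or length-2 `(low, high)` in
#'   Hz (bandpass).
#' @param fs Sampling rate in Hz.
#' @param kind `"lowpass"` or `"bandpass"`; inferred from `cutoff` length
#'   when missing.
#' @return Filtered signal, same shape as `x`.
#' @export
butterworth_filter <- function(x, order, cutoff, fs,
                               kind = if (length(cutoff) == 2) "bandpass" else "lowpass") {
  kind <- match.arg(kind, c("lowpass", "bandpass"))
  if (any(cutoff <= 0) || any(cutoff >= fs / 2))
    stop("filter cutoff(s) must lie in (0, fs/2)", call. = FALSE)
  w <- cutoff / (fs / 2)
  bt <- if (kind == "bandpass") {
    if (length(cutoff) != 2 || cutoff[1] >= cutoff[2])
      stop("bandpass needs cutoff = c(low, high) with low < high", call. = FALSE)
    signal::butter(order, w, type = "pass")
  } else {
    signal::butter(order, w, type = "low")
  }
  if (is.matrix(x)) {
    t(apply(x, 1L, zero_phase_apply, bt = bt))
  } else {
    zero_phase_apply(x, bt)
  }
}

# Forward-backward IIR pass with odd-reflection edge padding (the padding
# used by scipy's filtfilt); signal::filtfilt zero-pads only the tail, which
# leaves visible edge transients on 3-s windows.
zero_phase_apply <- function(x, bt, fs = NULL) {
  b <- bt$b
  a <- bt$a
  # low band edges settle slowly; pad generously (up to one second) so 3-s
  # windows keep clean boundaries
  npad <- max(3L * (max(length(a), length(b)) - 1L),
              min(128L, length(x) %/% 3L))
  n <- length(x)
  if (n <= npad)
    stop(sprintf("signal too short for zero-phase filtering (need > %d samples)",
                 npad), call. = FALSE)
  pre <- 2 * x[1] - x[seq(npad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - npad)]
  ext <- c(pre, x, post)
  # each pass starts from the step steady state of its first sample, so a
  # constant-offset signal (gravity-dominated vector magnitude) produces no
  # startup transient
  g0 <- sum(b) / sum(a)
  one_pass <- function(v) {
    as.numeric(signal::filter(b, a, v - v[1])) + v[1] * g0
  }
  y <- one_pass(ext)
  y <- rev(one_pass(rev(y)))
  y[seq(npad + 1L, npad + n)]
}

#' First principal component of a tri-axial window
#'
#' Mean-centers the three channels and projects onto the leading eigenvector
#' of the 3 x 3 channel covariance, giving an orientation-independent scalar
#' signal. The sign is fixed so the loading of the highest-variance channel
#' is non-negative, making the projection deterministic.
#'
#' @param triaxial_window 3 x n matrix.
#' @return Numeric vector of length n (dimensionless scale of g).
#' @export
pca_first_component <- function(triaxial_window) {
  w <- as_triaxial(triaxial_window)
  if (ncol(w) < 2) stop("PCA window needs at least 2 samples", call. = FALSE)
  centered <- w - rowMeans(w)
  vars <- apply(centered, 1L, function(r) sum(r^2))
  if (all(vars == 0))
    stop("degenerate input: zero variance in all channels", call. = FALSE)
  ev <- eigen(tcrossprod(centered) / (ncol(w) - 1), symmetric = TRUE)
  v <- ev$vectors[, 1L]
  if (v[which.max(vars)] < 0) v <- -v
  as.numeric(crossprod(centered, v))
}

#' Rolling coefficient of variation
#'
#' Per-sample coefficient of variation `sigma / mu` over a trailing window of
#' `span_s` seconds (stride one sample). The first `span_s * fs - 1` samples,
#' where no full trailing span exists, are back-filled with the first
#' full-span value. The mean is guarded by `eps` against pathological
#' near-zero denominators; on the low-passed vector magnitude the mean sits
#' near 1 g so the guard is inert in practice.
#'
#' @param x Numeric vector.
#' @param span_s Rolling span in seconds.
#' @param fs Sampling rate in Hz.
#' @param eps Denominator guard.
#' @return Numeric vector, same length as `x`.
#' @export
rolling_cov <- function(x, span_s = 1, fs = 128, eps = 1e-6) {
  n <- length(x)
  k <- as.integer(round(span_s * fs))
  if (n < k) stop("signal shorter than the rolling span", call. = FALSE)
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  idx <- k:n
  s1 <- cs[idx + 1L] - cs[idx - k + 1L]
  s2 <- cs2[idx + 1L] - cs2[idx - k + 1L]
  mu <- s1 / k
  # sample variance over the trailing span
  v <- pmax((s2 - s1^2 / k) / (k - 1), 0)
  cv <- sqrt(v) / pmax(abs(mu), eps)
  c(rep(cv[1L], k - 1L), cv)
}

#' Root mean square
#'
#' @param x Numeric vector (non-empty).
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) {
  if (length(x) < 1) stop("rms of empty signal", call. = FALSE)
  sqrt(mean(x^2))
}

#' Scaled mean squared jerk
#'
#' Smoothness measure of one window: jerk is the first forward difference of
#' the (band-passed vector-magnitude) acceleration scaled by `fs`, and the
#' mean squared jerk is normalized by the window duration squared and the
#' squared maximum of the signal, `mean(j^2) * T^2 / max(s)^2`, giving a
#' dimensionless quantity that is invariant to signal amplitude. Higher
#' values indicate movement with sudden, frequent accelerations (halting);
#' lower values indicate smooth movement.
#'
#' @param x Numeric vector (band-passed vector magnitude of one window), g.
#' @param fs Sampling rate in Hz.
#' @return Dimensionless scalar.
#' @export
scaled_mean_squared_jerk <- function(x, fs) {
  if (length(x) < 2) stop("jerk needs at least 2 samples", call. = FALSE)
  mx <- max(abs(x))
  if (mx == 0) stop("degenerate input: zero signal", call. = FALSE)
  j <- diff(x) * fs
  duration <- length(x) / fs
  mean(j^2) * duration^2 / mx^2
}
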