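#' Segment script for the synthetic-signal generator
#'
#' Describes a visit as an ordered sequence of latent motor states with
#' per-segment generating parameters. States: `REST` (gravity plus sensor
#' noise), `TREMOR` (resting tremor: amplitude-modulated oscillation at a
#' fundamental in the 3--8 Hz band, strongest in the gyroscope), `MOVE`
#' (voluntary sub-3 Hz hand movement with controllable jerkiness), `GAIT`
#' (cadence-periodic step impulses plus an arm-swing harmonic at half the
#' step rate).
#'
#' @param state Character vector of states (`REST`, `TREMOR`, `MOVE`,
#'   `GAIT`).
#' @param duration_s Segment durations, seconds (> 0).
#' @param tremor_hz Tremor fundamental, Hz (must lie in `[3, 8]`).
#' @param tremor_amp_g Tremor vector-magnitude envelope, g.
#' @param gyro_tremor_dps Gyroscope tremor amplitude, deg/s.
#' @param move_hz,move_amp_g Voluntary-movement fundamental (Hz) and
#'   amplitude (g).
#' @param jerkiness In `[0, 1]`: 0 = smooth sinusoidal movement, larger
#'   values insert halting on/off bursts that raise the jerk measure.
#' @param cadence_spm Gait cadence, steps/min (> 0).
#' @param step_amp_g Step-impulse amplitude, g.
#' @param swing_amp_g Arm-swing amplitude at half the step rate, g.
#' @param physio_dps Physiological-tremor gyroscope amplitude during `REST`
#'   segments, deg/s (slow amplitude modulation, +/- 50%); its accelerometer
#'   counterpart is small (`0.002 g` per deg/s). Default 0 (off).
#' @param physio_hz Physiological-tremor frequency, Hz.
#' @return Object of class `segment_script` (a data frame).
#' @export
segment_script <- function(state, duration_s, tremor_hz = 5,
                           tremor_amp_g = 0.2, gyro_tremor_dps = 20,
                           move_hz = 1, move_amp_g = 0.2, jerkiness = 0,
                           cadence_spm = 112, step_amp_g = 0.3,
                           swing_amp_g = 0.15, physio_dps = 0,
                           physio_hz = 7.2) {
  state <- match.arg(toupper(state), c("REST", "TREMOR", "MOVE", "GAIT"),
                     several.ok = TRUE)
  df <- data.frame(state = state, duration_s = duration_s,
                   tremor_hz = tremor_hz, tremor_amp_g = tremor_amp_g,
                   gyro_tremor_dps = gyro_tremor_dps, move_hz = move_hz,
                   move_amp_g = move_amp_g, jerkiness = jerkiness,
                   cadence_spm = cadence_spm, step_amp_g = step_amp_g,
                   swing_amp_g = swing_amp_g,
                   physio_dps = physio_dps, physio_hz = physio_hz,
                   stringsAsFactors = FALSE)
  if (any(df$duration_s <= 0))
    stop("script error: segment durations must be positive", call. = FALSE)
  if (any(df$state == "TREMOR" & (df$tremor_hz < 3 | df$tremor_hz > 8)))
    stop("script error: tremor frequency must lie in [3, 8] Hz", call. = FALSE)
  if (any(df$state == "GAIT" & df$cadence_spm <= 0))
    stop("script error: cadence must be positive", call. = FALSE)
  if (any(df$jerkiness < 0 | df$jerkiness > 1))
    stop("script error: jerkiness must lie in [0, 1]", call. = FALSE)
  structure(df, class = c("segment_script", "data.frame"))
}

random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# movement directions keep a substantial gravity-parallel component: wrist
# movement tilts the device through the gravity field, so purely
# gravity-orthogonal acceleration (which leaves the vector magnitude almost
# unchanged) is not physically representative
random_movement_direction <- function(gravity, min_parallel = 0.4) {
  repeat {
    u <- random_unit_vector()
    if (abs(sum(u * gravity)) >= min_parallel) return(u)
  }
}

# raised-cosine activation envelope for one segment within the recording,
# ramping over `fade_s` at interior boundaries
segment_envelope <- function(n_total, i0, i1, fs, fade_s = 0.25) {
  env <- numeric(n_total)
  env[i0:i1] <- 1
  nf <- round(fade_s * fs)
  ramp <- (1 - cos(pi * seq_len(nf) / nf)) / 2
  if (i0 > 1) env[i0:(i0 + nf - 1L)] <- ramp
  if (i1 < n_total) env[(i1 - nf + 1L):i1] <- rev(ramp)
  env
}

#' Simulate a wrist inertial recording with per-sample ground truth
#'
#' Generates accelerometer (and gyroscope) streams from a [segment_script()]:
#' a per-subject randomized gravity orientation, state-specific oscillatory
#' components along random directions, white sensor noise, and smooth 0.25-s
#' crossfades at segment boundaries. Fully reproducible from `(script,
#' seed)`.
#'
#' @param script A [segment_script()].
#' @param seed Integer seed.
#' @param config A [motor_config()] (supplies `fs`).
#' @param noise_sd_g Accelerometer white-noise standard deviation, g.
#' @param gyro_noise_sd_dps Gyroscope white-noise standard deviation, deg/s.
#' @param with_gyro Generate gyroscope channels?
#' @param subject_id,cohort,visit Metadata for the recording.
#' @return List with `recording` (an [inertial_recording()]) and `truth`
#'   (per-sample `state` factor, ground-truth `intervals`, the script, the
#'   seed and generator parameters).
#' @export
simulate_recording <- function(script, seed, config = motor_config(),
                               noise_sd_g = 0.002, gyro_noise_sd_dps = 0.5,
                               with_gyro = TRUE, subject_id = "S01",
                               cohort = c("HC", "PD"), visit = 1L) {
  stopifnot(inherits(script, "segment_script"))
  fs <- config$fs
  set.seed(derive_seed(seed, 0))
  n_seg <- round(script$duration_s * fs)
  n <- sum(n_seg)
  t <- (seq_len(n) - 1L) / fs
  gravity <- random_unit_vector()
  accel <- gravity %o% rep(1, n)
  gyro <- matrix(0, 3, n)
  state <- character(n)
  ends <- cumsum(n_seg)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  for (k in seq_len(nrow(script))) {
    i0 <- starts[k]; i1 <- ends[k]
    idx <- i0:i1
    state[idx] <- script$state[k]
    env <- segment_envelope(n, i0, i1, fs)[idx]
    ts <- t[idx]
    comp <- matrix(0, 3, length(idx))
    gcomp <- matrix(0, 3, length(idx))
    if (script$state[k] == "REST" && script$physio_dps[k] > 0) {
      # physiological tremor: low-amplitude high-frequency oscillation,
      # prominent in the gyroscope but barely visible in the accelerometer
      u <- random_unit_vector()
      ph <- stats::runif(2, 0, 2 * pi)
      mod <- 1 + 0.5 * sin(2 * pi * 0.05 * ts + ph[2])
      osc <- mod * sin(2 * pi * script$physio_hz[k] * ts + ph[1])
      comp <- u %o% (0.002 * script$physio_dps[k] * osc)
      gcomp <- random_unit_vector() %o% (script$physio_dps[k] * osc)
    } else if (script$state[k] == "TREMOR") {
      # amplitude-modulated oscillation whose device-frame direction drifts
      # slowly (pronation-supination tremor under small posture shifts)
      u <- random_unit_vector()
      u_perp <- random_unit_vector()
      u_perp <- u_perp - sum(u_perp * u) * u
      u_perp <- u_perp / sqrt(sum(u_perp^2))
      ph <- stats::runif(3, 0, 2 * pi)
      theta <- 0.5 * sin(2 * pi * 0.05 * ts + ph[3])
      mod <- 1 + 0.2 * sin(2 * pi * 0.3 * ts + ph[2])
      osc <- script$tremor_amp_g[k] * mod *
        sin(2 * pi * script$tremor_hz[k] * ts + ph[1])
      comp <- u %o% (cos(theta) * osc) + u_perp %o% (sin(theta) * osc)
      gcomp <- random_unit_vector() %o%
        (script$gyro_tremor_dps[k] * mod *
           sin(2 * pi * script$tremor_hz[k] * ts + stats::runif(1, 0, 2 * pi)))
    } else if (script$state[k] == "MOVE") {
      # voluntary movement: an irregular band-limited trajectory with a
      # weaker rhythmic component -- unlike gait it carries no sustained
      # periodicity
      u <- random_movement_direction(gravity)
      ph <- stats::runif(1, 0, 2 * pi)
      z <- stats::rnorm(length(idx))
      drift <- stats::rnorm(length(idx))
      if (length(idx) > 48) {
        z <- butterworth_filter(z, 2, c(0.3, 2.5), fs)
        z <- z / max(rms(z), 1e-9)
        drift <- butterworth_filter(drift, 2, 0.5, fs, kind = "lowpass")
        drift <- drift / max(rms(drift), 1e-9)
      } else {
        z <- z * 0
        drift <- drift * 0
      }
      # tempo is not metronomic: the instantaneous rhythm frequency wanders
      # by ~25%, so no sustained cadence-like periodicity builds up
      inst_f <- script$move_hz[k] * (1 + 0.25 * drift)
      phase <- 2 * pi * cumsum(inst_f) / fs + ph
      base <- script$move_amp_g[k] * (0.4 * sin(phase) + 0.7 * z)
      if (script$jerkiness[k] > 0) {
        # hesitant movement: rapid corrective accelerations near the top of
        # the movement band (raising jerk) plus partial halting bursts
        base <- base + script$jerkiness[k] * 0.5 * script$move_amp_g[k] *
          sin(2 * pi * 3.1 * ts + stats::runif(1, 0, 2 * pi))
        gate <- as.numeric(sin(2 * pi * 0.8 * ts + ph) > -0.3)
        base <- base * (1 - 0.5 * script$jerkiness[k] * (1 - gate))
      }
      comp <- u %o% base
      gcomp <- random_unit_vector() %o%
        (10 * sin(2 * pi * script$move_hz[k] * ts + stats::runif(1, 0, 2 * pi)))
    } else if (script$state[k] == "GAIT") {
      f_step <- script$cadence_spm[k] / 60
      u_swing <- random_movement_direction(gravity)
      ph <- stats::runif(2, 0, 2 * pi)
      swing <- script$swing_amp_g[k] * sin(2 * pi * f_step / 2 * ts + ph[1])
      # periodic step impulses (Gaussian pulses at the step rate), zero-mean
      phase <- (ts * f_step + ph[2] / (2 * pi)) %% 1
      pulse <- exp(-((phase - 0.5)^2) / (2 * 0.06^2))
      pulse <- pulse - mean(pulse)
      comp <- u_swing %o% swing + gravity %o% (script$step_amp_g[k] * pulse)
      gcomp <- random_unit_vector() %o%
        (30 * sin(2 * pi * f_step / 2 * ts + ph[1]))
    }
    accel[, idx] <- accel[, idx] + comp * rep(env, each = 3)
    gyro[, idx] <- gyro[, idx] + gcomp * rep(env, each = 3)
  }
  accel <- accel + matrix(stats::rnorm(3 * n, sd = noise_sd_g), 3, n)
  gyro <- gyro + matrix(stats::rnorm(3 * n, sd = gyro_noise_sd_dps), 3, n)
  cohort <- match.arg(cohort)
  rec <- inertial_recording(t, accel, if (with_gyro) gyro, fs = fs,
                            subject_id = subject_id, cohort = cohort,
                            visit = visit)
  truth_int <- interval_set((starts - 1L) / fs, ends / fs, script$state,
                            duration_s = n / fs)
  list(recording = rec,
       truth = list(state = factor(state,
                                   levels = c("REST", "TREMOR", "MOVE", "GAIT")),
                    intervals = truth_int, script = script, seed = seed,
                    gravity = gravity, noise_sd_g = noise_sd_g))
}

# window-aligned visit script: contiguous bouts of each state whose 3-s
# block counts hit the requested state fractions
cohort_visit_script <- function(n_blocks, frac_tremor, frac_move, frac_gait,
                                block_s = 3, ...) {
  n_trem <- round(frac_tremor * n_blocks)
  n_gait <- round(frac_gait * n_blocks)
  n_move <- round(frac_move * n_blocks)
  n_rest <- n_blocks - n_trem - n_gait - n_move
  stopifnot(n_rest >= 0)
  # interleave bouts: rest / tremor / rest / move / rest / gait / ...
  pieces <- list()
  add <- function(st, nb) if (nb > 0) pieces[[length(pieces) + 1L]] <<-
      c(st, nb)
  half <- function(nb) c(ceiling(nb / 2), floor(nb / 2))
  tr <- half(n_trem); mv <- half(n_move); gt <- half(n_gait)
  rest4 <- diff(round(seq(0, n_rest, length.out = 5)))
  add("REST", rest4[1]); add("TREMOR", tr[1]); add("MOVE", mv[1])
  add("REST", rest4[2]); add("GAIT", gt[1]); add("TREMOR", tr[2])
  add("REST", rest4[3]); add("MOVE", mv[2]); add("GAIT", gt[2])
  add("REST", rest4[4])
  st <- vapply(pieces, function(p) p[1], character(1))
  nb <- as.integer(vapply(pieces, function(p) p[2], character(1)))
  segment_script(st, nb * block_s, ...)
}

#' Simulate a cohort of subjects
#'
#' Generates one visit per subject (optionally a paired second visit with
#' scaled severity, emulating OFF-state worsening). Healthy controls carry
#' no tremor; PD subjects draw tremor constancy, tremor amplitude and
#' movement amplitude from configurable severity distributions. Device
#' orientation, segment directions and noise level are randomized per
#' subject; per-subject seeds derive from the base seed by a counter scheme,
#' so cohorts are reproducible and extensible.
#'
#' @param n_hc,n_pd Numbers of healthy-control and PD subjects.
#' @param seed Base integer seed.
#' @param config A [motor_config()].
#' @param visit_s Visit duration, seconds (multiple of the window length).
#' @param constancy_range PD tremor-constancy range (fraction of visit),
#'   sampled uniformly.
#' @param tremor_amp_range PD tremor vector-magnitude envelope range, g,
#'   sampled log-uniformly so the cohort spans barely perceptible to overt
#'   tremor; the gyroscope tremor amplitude is tied to it (100 deg/s per g).
#' @param move_amp_range Voluntary movement amplitude range, g (severity
#'   lowers amplitude for PD subjects).
#' @param move_hz_range Range of the rhythmic component of voluntary
#'   movement, Hz.
#' @param frac_move,frac_gait Fractions of the visit spent in voluntary
#'   movement and gait.
#' @param off_scale If not `NULL`, each subject gets a second visit with
#'   tremor constancy, tremor amplitude and gyro amplitude scaled by this
#'   factor (> 1 emulates OFF state).
#' @return List of per-subject entries: `recording`, `truth`, and `params`
#'   (the drawn severity parameters).
#' @export
simulate_cohort <- function(n_hc, n_pd, seed, config = motor_config(),
                            visit_s = 360, constancy_range = c(0.1, 0.5),
                            tremor_amp_range = c(0.02, 0.3),
                            move_amp_range = c(0.1, 0.45),
                            move_hz_range = c(0.6, 1.4),
                            frac_move = 0.2, frac_gait = 0.15,
                            off_scale = NULL) {
  if (n_hc + n_pd < 2)
    stop("script error: cohort needs at least 2 subjects", call. = FALSE)
  n_blocks <- round(visit_s / config$window_length_s)
  subjects <- list()
  idx <- 0L
  for (i in seq_len(n_hc + n_pd)) {
    is_pd <- i > n_hc
    sid <- sprintf("%s%02d", if (is_pd) "PD" else "HC", i)
    set.seed(derive_seed(seed, 1000 + i))
    constancy <- if (is_pd) stats::runif(1, constancy_range[1],
                                         constancy_range[2]) else 0
    tremor_amp <- if (is_pd) exp(stats::runif(1, log(tremor_amp_range[1]),
                                              log(tremor_amp_range[2]))) else 0.1
    move_amp <- stats::runif(1, move_amp_range[1], move_amp_range[2])
    jerk <- if (is_pd) stats::runif(1, 0.3, 0.8) else stats::runif(1, 0, 0.3)
    cadence <- stats::runif(1, 100, 125)
    step_amp <- stats::runif(1, 0.2, 0.4)
    swing_amp <- stats::runif(1, 0.08, 0.25)
    noise_sd <- stats::runif(1, 0.0015, 0.003)
    tremor_hz <- stats::runif(1, 4, 6.5)
    # physiological tremor: stronger in (younger) controls than in the PD
    # group, and never close to parkinsonian tremor amplitude
    physio_dps <- if (is_pd) stats::runif(1, 0.3, 1.5)
                  else stats::runif(1, 1.2, 3.0)
    physio_hz <- stats::runif(1, 6.5, 8.0)
    visits <- if (is.null(off_scale)) 1L else 1:2
    for (v in visits) {
      sc <- if (v == 2) off_scale else 1
      script <- cohort_visit_script(
        n_blocks, frac_tremor = min(constancy * sc, 0.6),
        frac_move = frac_move, frac_gait = frac_gait,
        block_s = config$window_length_s,
        tremor_hz = tremor_hz, tremor_amp_g = tremor_amp * sc,
        gyro_tremor_dps = 100 * tremor_amp * sc,
        move_hz = stats::runif(1, move_hz_range[1], move_hz_range[2]),
        move_amp_g = move_amp, jerkiness = jerk, cadence_spm = cadence,
        step_amp_g = step_amp, swing_amp_g = swing_amp,
        physio_dps = physio_dps, physio_hz = physio_hz)
      sim <- simulate_recording(script, derive_seed(seed, 2000 + 10 * i + v),
                                config, noise_sd_g = noise_sd,
                                subject_id = sid,
                                cohort = if (is_pd) "PD" else "HC",
                                visit = v)
      idx <- idx + 1L
      subjects[[idx]] <- c(sim, list(params = list(
        subject_id = sid, cohort = if (is_pd) "PD" else "HC", visit = v,
        constancy = min(constancy * sc, 0.6), tremor_amp_g = tremor_amp * sc,
        move_amp_g = move_amp, jerkiness = jerk, cadence_spm = cadence,
        tremor_hz = tremor_hz, noise_sd_g = noise_sd,
        physio_dps = physio_dps, physio_hz = physio_hz)))
    }
  }
  subjects
}
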