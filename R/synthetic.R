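#' Define a gesture archetype for the synthetic generator
#'
#' The generator models sEMG activity as amplitude-modulated band-limited
#' Gaussian noise (the standard surrogate for an sEMG interference pattern)
#' plus a deterministic low-frequency oscillation phase-locked to movement
#' onset, which carries the shared low-frequency structure that repeated
#' executions of the same gesture exhibit. An archetype fixes, per gesture:
#' the spatial activation topography over channels, the force level (the
#' amplitude multiplier that separates superclasses), the activity passband
#' and the low-frequency oscillation.
#'
#' @param gesture_id Positive integer gesture id.
#' @param superclass_id Superclass the gesture belongs to.
#' @param channel_weights Non-negative per-channel activation weights (at
#'   least one positive entry).
#' @param force_scale Positive amplitude multiplier encoding force level
#'   (highest for functional/grasping, middle for wrist, lowest for finger
#'   movements).
#' @param band Length-2 passband (low_hz, high_hz) of the activity.
#' @param tone_hz Frequency (Hz) of the deterministic low-frequency
#'   oscillation; must lie inside `band`.
#' @param tone_weight Amplitude of the oscillation relative to the unit-sd
#'   stochastic component.
#' @return A `gesture_archetype` list.
#' @export
gesture_archetype <- function(gesture_id, superclass_id, channel_weights,
                              force_scale = 1, band = c(2, 45),
                              tone_hz = 3, tone_weight = 1) {
  stopifnot(gesture_id > 0, superclass_id > 0)
  channel_weights <- as.numeric(channel_weights)
  if (any(channel_weights < 0) || !any(channel_weights > 0))
    stop("channel_weights must be non-negative with at least one positive entry",
         call. = FALSE)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop("band must be (low_hz, high_hz) with 0 < low < high", call. = FALSE)
  if (tone_hz < band[1] || tone_hz > band[2])
    stop("tone_hz must lie inside the activity band", call. = FALSE)
  structure(list(gesture_id = as.integer(gesture_id),
                 superclass_id = as.integer(superclass_id),
                 channel_weights = channel_weights,
                 force_scale = as.numeric(force_scale),
                 band = as.numeric(band),
                 tone_hz = as.numeric(tone_hz),
                 tone_weight = as.numeric(tone_weight)),
            class = "gesture_archetype")
}

#' Define a simulation plan
#'
#' A plan schedules `n_repetitions` executions of every archetype as
#' alternating rest/active blocks (gestures interleaved in round-robin order,
#' one trailing rest), with optional uniform label misalignment emulating
#' subject response-time lag between the stimulus cue and the actual
#' movement.
#'
#' @param archetypes List of [gesture_archetype()]s (may be empty).
#' @param n_repetitions Repetitions per gesture (>= 1).
#' @param active_ms,rest_ms Active / rest block durations in ms.
#' @param label_jitter_ms Maximum absolute misalignment of the emitted label
#'   onsets/offsets relative to true activity, in ms (uniform, independent
#'   per edge).
#' @param noise_sd Baseline (rest) Gaussian noise SD, present everywhere.
#' @param fs Sampling rate in Hz.
#' @param n_channels Channel count; defaults to the archetype weight length.
#' @param seed Integer seed; the same plan and seed give bit-identical output.
#' @return A `simulation_plan` list.
#' @export
simulation_plan <- function(archetypes, n_repetitions = 10L,
                            active_ms = 600, rest_ms = 400,
                            label_jitter_ms = 0, noise_sd = 0.1,
                            fs = 100, n_channels = NULL, seed = 1L) {
  stopifnot(n_repetitions >= 1L, active_ms > 0, rest_ms >= 0,
            label_jitter_ms >= 0, noise_sd >= 0, fs > 0)
  if (is.null(n_channels)) {
    n_channels <- if (length(archetypes)) length(archetypes[[1L]]$channel_weights) else 1L
  }
  for (a in archetypes) {
    if (length(a$channel_weights) != n_channels)
      stop("archetype ", a$gesture_id, ": channel_weights length != n_channels",
           call. = FALSE)
    if (a$band[2] >= fs / 2)
      stop("archetype ", a$gesture_id, ": band upper edge must be below fs/2",
           call. = FALSE)
  }
  ids <- vapply(archetypes, `[[`, integer(1), "gesture_id")
  if (anyDuplicated(ids)) stop("duplicate gesture_id in archetypes", call. = FALSE)
  structure(list(archetypes = archetypes,
                 n_repetitions = as.integer(n_repetitions),
                 active_ms = active_ms, rest_ms = rest_ms,
                 label_jitter_ms = label_jitter_ms, noise_sd = noise_sd,
                 fs = fs, n_channels = as.integer(n_channels),
                 seed = as.integer(seed)),
            class = "simulation_plan")
}

plan_block_samples <- function(plan) {
  c(rest = round(plan$rest_ms * plan$fs / 1000),
    active = round(plan$active_ms * plan$fs / 1000))
}

# Round-robin block order: rep 1 of every gesture, then rep 2, ...
plan_block_gestures <- function(plan) {
  ng <- length(plan$archetypes)
  if (ng == 0L) return(integer(0))
  rep(seq_len(ng), times = plan$n_repetitions)
}

#' True activity intervals of a plan
#'
#' Ground-truth (pre-jitter) activity intervals, 0-based and half-open, in
#' schedule order. These are what the Teager relabeling stage is supposed to
#' recover from the signal.
#'
#' @param plan A [simulation_plan()].
#' @return data.frame with columns `start_sample`, `end_sample`, `gesture_id`.
#' @export
true_intervals <- function(plan) {
  bs <- plan_block_samples(plan)
  g <- plan_block_gestures(plan)
  if (!length(g))
    return(data.frame(start_sample = integer(0), end_sample = integer(0),
                      gesture_id = integer(0)))
  block_len <- sum(bs)
  starts <- (seq_along(g) - 1L) * block_len + bs[["rest"]]
  data.frame(start_sample = as.integer(starts),
             end_sample = as.integer(starts + bs[["active"]]),
             gesture_id = vapply(plan$archetypes[g], `[[`, integer(1),
                                 "gesture_id"))
}

trapezoid_envelope <- function(n, ramp_frac = 0.1) {
  ramp <- max(1L, round(ramp_frac * n))
  env <- rep(1, n)
  up <- seq_len(min(ramp, n))
  env[up] <- up / ramp
  down <- seq_len(min(ramp, n))
  env[n - down + 1L] <- pmin(env[n - down + 1L], down / ramp)
  env
}

band_limited_noise <- function(n, band, fs) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n + 2L * n))[(n + 1L):(2L * n)]
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Simulate a multichannel sEMG recording
#'
#' Baseline Gaussian noise everywhere; during each active block the gesture's
#' archetype adds `force_scale * channel_weights[c] *` (trapezoid envelope,
#' 10% ramps) `* (tone_weight * sin(2*pi*tone_hz*t) + band-limited unit-sd
#' Gaussian noise)` per channel. Emitted labels are the true intervals with
#' independent uniform onset/offset misalignment up to `label_jitter_ms`.
#'
#' @param plan A [simulation_plan()].
#' @return An [emg_recording()] (labels carry the jittered stream; use
#'   [true_intervals()] for ground truth).
#' @export
simulate_recording <- function(plan) {
  stopifnot(inherits(plan, "simulation_plan"))
  bs <- plan_block_samples(plan)
  g <- plan_block_gestures(plan)
  block_len <- sum(bs)
  n <- length(g) * block_len + bs[["rest"]]
  n <- max(n, 1L)
  C <- plan$n_channels
  set.seed(plan$seed)
  signal <- matrix(if (plan$noise_sd > 0) stats::rnorm(n * C, sd = plan$noise_sd)
                   else 0, n, C)
  labels <- integer(n)
  iv <- true_intervals(plan)
  jit_n <- round(plan$label_jitter_ms * plan$fs / 1000)
  prev_end <- 0L
  for (b in seq_along(g)) {
    a <- plan$archetypes[[g[b]]]
    act_n <- bs[["active"]]
    on <- iv$start_sample[b]
    env <- trapezoid_envelope(act_n)
    tt <- (seq_len(act_n) - 1L) / plan$fs
    tone <- sin(2 * pi * a$tone_hz * tt)
    rows <- (on + 1L):(on + act_n)
    for (ch in seq_len(C)) {
      w <- a$channel_weights[ch]
      if (w == 0) next
      carrier <- band_limited_noise(act_n, a$band, plan$fs)
      signal[rows, ch] <- signal[rows, ch] +
        a$force_scale * w * env * (a$tone_weight * tone + carrier)
    }
    e_on <- on
    e_off <- iv$end_sample[b]
    if (jit_n > 0) {
      j <- round(stats::runif(2, -jit_n, jit_n))
      e_on <- on + j[1L]
      e_off <- iv$end_sample[b] + j[2L]
    }
    e_on <- max(e_on, prev_end, 0L)
    e_off <- min(max(e_off, e_on + 1L), n)
    labels[(e_on + 1L):e_off] <- a$gesture_id
    prev_end <- e_off
  }
  emg_recording(signal, fs = plan$fs, labels = labels,
                subject_id = "synthetic",
                exercise_id = sprintf("sim-seed%d", plan$seed))
}

#' Derive the gesture taxonomy implied by a plan's archetypes
#' @param plan A [simulation_plan()] with at least two superclasses.
#' @return A [gesture_taxonomy()].
#' @export
taxonomy_from_plan <- function(plan) {
  map <- vapply(plan$archetypes, `[[`, integer(1), "superclass_id")
  names(map) <- vapply(plan$archetypes, `[[`, integer(1), "gesture_id")
  gesture_taxonomy(map)
}
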