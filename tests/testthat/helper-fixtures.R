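# Shared fixtures, built in code. Heavier objects are cached per session so
# several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Two superclasses x two gestures, small: enough windows for 3-fold CV.
small_plan <- function(seed = 11L, n_repetitions = 12L, label_jitter_ms = 100) {
  arch <- list(
    gesture_archetype(1L, 1L, c(1, 0.5, 0.2, 0.2), force_scale = 1,
                      tone_hz = 2.5),
    gesture_archetype(2L, 1L, c(0.2, 0.2, 0.5, 1), force_scale = 1,
                      tone_hz = 4.5),
    gesture_archetype(3L, 2L, c(1, 0.5, 0.2, 0.2), force_scale = 4,
                      tone_hz = 2.5),
    gesture_archetype(4L, 2L, c(0.2, 0.2, 0.5, 1), force_scale = 4,
                      tone_hz = 4.5))
  simulation_plan(arch, n_repetitions = n_repetitions, active_ms = 600,
                  rest_ms = 400, label_jitter_ms = label_jitter_ms,
                  noise_sd = 0.1, fs = 100, seed = seed)
}

# Fast training budget for pipeline tests (not the benchmark conditions).
fast_config <- function(seed = 11L, epochs = 8L, patience = 3L, ...) {
  emg_config(seed = seed, epochs = epochs, patience = patience, ...)
}

small_dataset <- function() {
  cached("small_ds", function() {
    plan <- small_plan()
    rec <- simulate_recording(plan)
    build_window_dataset(rec, fast_config(), taxonomy_from_plan(plan))
  })
}
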