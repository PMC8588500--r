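#' The package's synthetic gesture-recognition benchmark
#'
#' A fixed study design used throughout the tests and examples: 3
#' superclasses (finger, wrist, functional movements) x 4 gestures each,
#' 40 repetitions per gesture, 4 electrode channels at 100 Hz. Superclasses
#' are separated by force level (amplitude scales 1 / 3 / 9, lowest for
#' finger and highest for functional movements); gestures within a
#' superclass differ by their channel activation topography and by the
#' frequency of the low-frequency oscillation phase-locked to onset
#' (2.5-5.5 Hz). Activity blocks last 600 ms with 400 ms rest, and the
#' emitted labels are misaligned by up to 200 ms, emulating subject
#' response-time lag.
#'
#' @param seed Integer seed for the generator.
#' @param n_repetitions Repetitions per gesture (default 40).
#' @param n_superclasses Number of superclasses (default 3, max 3).
#' @param gestures_per_superclass Gestures per superclass (default 4, max 4).
#' @param label_jitter_ms Label misalignment bound in ms (default 200).
#' @return A [simulation_plan()].
#' @export
synthetic_benchmark_plan <- function(seed = 1L, n_repetitions = 40L,
                                     n_superclasses = 3L,
                                     gestures_per_superclass = 4L,
                                     label_jitter_ms = 200) {
  stopifnot(n_superclasses >= 2L, n_superclasses <= 3L,
            gestures_per_superclass >= 2L, gestures_per_superclass <= 4L)
  force_scales <- c(1, 3, 9)        # finger, wrist, functional
  tone_freqs <- c(2.5, 3.5, 4.5, 5.5)
  n_ch <- 4L
  archetypes <- list()
  gid <- 0L
  for (s in seq_len(n_superclasses)) {
    for (g in seq_len(gestures_per_superclass)) {
      gid <- gid + 1L
      w <- rep(0.3, n_ch)
      w[g] <- 1
      w[(g %% n_ch) + 1L] <- 0.6   # asymmetric two-channel topography
      archetypes[[gid]] <- gesture_archetype(
        gesture_id = gid, superclass_id = s, channel_weights = w,
        force_scale = force_scales[s], band = c(2, 45),
        tone_hz = tone_freqs[g], tone_weight = 1)
    }
  }
  simulation_plan(archetypes, n_repetitions = n_repetitions,
                  active_ms = 600, rest_ms = 400,
                  label_jitter_ms = label_jitter_ms, noise_sd = 0.1,
                  fs = 100, n_channels = n_ch, seed = seed)
}

#' Run the synthetic benchmark end to end
#'
#' Simulates the benchmark recording, builds the window dataset (z-score,
#' Teager relabel, 400 ms windows, K-mode MVMD) and cross-validates the
#' two-stage framework.
#'
#' @param seed Seed for generator, shuffling and training.
#' @param folds Cross-validation folds.
#' @param config Optional [emg_config()] override (its seed is replaced).
#' @param permute_labels Permute gesture labels before evaluation (chance-
#'   level control; the permutation respects nothing, superclasses follow
#'   the permuted gesture).
#' @return List with `report` (an `eval_report`), `dataset`, `plan`.
#' @export
run_benchmark <- function(seed = 1L, folds = 10L, config = NULL,
                          permute_labels = FALSE) {
  plan <- synthetic_benchmark_plan(seed = seed)
  rec <- simulate_recording(plan)
  taxonomy <- taxonomy_from_plan(plan)
  if (is.null(config)) config <- emg_config(seed = seed)
  config$seed <- as.integer(seed)
  ds <- build_window_dataset(rec, config, taxonomy)
  if (permute_labels) {
    set.seed(seed + 1L)
    perm <- sample(seq_along(ds$labels))
    ds$labels <- ds$labels[perm]
    ds$superclass <- superclass_of(taxonomy, ds$labels)
    for (i in seq_along(ds$windows)) {
      ds$windows[[i]]$label <- ds$labels[i]
      ds$windows[[i]]$superclass <- ds$superclass[i]
    }
    ds$features$label <- ds$labels
    ds$features$superclass <- ds$superclass
  }
  report <- crossvalidate(ds, config, folds = folds)
  list(report = report, dataset = ds, plan = plan)
}
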