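#' Default run configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the framework's standard operating point: 400 ms analysis windows cut
#' without overlap and a four-mode decomposition; the remaining knobs are
#' package choices documented in the methods vignette.
#'
#' @param window_ms Analysis window length in milliseconds (no overlap).
#' @param n_modes Number of MVMD modes K.
#' @param alpha MVMD bandwidth penalty (positive).
#' @param tau MVMD dual-ascent step (>= 0; 0 gives a noise-robust, exactly
#'   relaxed reconstruction).
#' @param tol MVMD convergence threshold (positive).
#' @param max_iter MVMD iteration cap.
#' @param teager_smooth_N Moving-average width for the Teager energy stream,
#'   in samples; `NULL` means 0.1 s worth of samples.
#' @param teager_threshold Hard energy threshold; `NULL` means automatic
#'   (5x the rest-level energy, see [auto_threshold()]).
#' @param min_active_ms Minimum duration (ms) a threshold crossing must last.
#' @param feature_threshold Dead-band T for the count features (ZC/SSC/WA),
#'   on the z-scored amplitude scale.
#' @param stage1_features Time-domain feature names used for superclass
#'   routing (default the RMS + MAV + DASDV selection).
#' @param stage1_method One of `"svm"`, `"rf"`, `"dt"`, `"knn"`, `"nb"`, `"lda"`.
#' @param epochs,batch_size,learning_rate,patience,val_fraction Stage-2
#'   network training budget: Adam optimizer, early stopping on validation
#'   loss with best-weight restore.
#' @param seed Integer seed governing every stochastic step.
#' @param superclass_map Named vector mapping gesture id to superclass id
#'   (may be `NULL` until a taxonomy is known).
#' @return A list of class `emg_config`.
#' @examples
#' cfg <- emg_config(seed = 7)
#' cfg$window_ms
#' @export
emg_config <- function(window_ms = 400,
                       n_modes = 4L,
                       alpha = 2000,
                       tau = 0,
                       tol = 1e-7,
                       max_iter = 500L,
                       teager_smooth_N = NULL,
                       teager_threshold = NULL,
                       min_active_ms = 50,
                       feature_threshold = 0.01,
                       stage1_features = c("RMS", "MAV", "DASDV"),
                       stage1_method = "svm",
                       epochs = 30L,
                       batch_size = 256L,
                       learning_rate = 1e-3,
                       patience = 5L,
                       val_fraction = 0.1,
                       seed = 1L,
                       superclass_map = NULL) {
  cfg <- structure(list(
    window_ms = window_ms, n_modes = as.integer(n_modes), alpha = alpha,
    tau = tau, tol = tol, max_iter = as.integer(max_iter),
    teager_smooth_N = teager_smooth_N, teager_threshold = teager_threshold,
    min_active_ms = min_active_ms, feature_threshold = feature_threshold,
    stage1_features = stage1_features, stage1_method = stage1_method,
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, patience = as.integer(patience),
    val_fraction = val_fraction, seed = as.integer(seed),
    superclass_map = superclass_map), class = "emg_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  bad <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)
  if (!is.numeric(cfg$window_ms) || cfg$window_ms <= 0) bad("window_ms must be > 0")
  if (cfg$n_modes < 1L) bad("n_modes (K) must be >= 1")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0) bad("alpha must be > 0")
  if (cfg$tau < 0) bad("tau must be >= 0")
  if (cfg$tol <= 0) bad("tol must be > 0")
  if (cfg$max_iter < 1L) bad("max_iter must be >= 1")
  if (!is.null(cfg$teager_smooth_N) && cfg$teager_smooth_N < 1)
    bad("teager_smooth_N must be >= 1 sample")
  if (!is.null(cfg$teager_threshold) && cfg$teager_threshold <= 0)
    bad("teager_threshold must be > 0")
  if (cfg$min_active_ms <= 0) bad("min_active_ms must be > 0")
  if (!cfg$stage1_method %in% c("svm", "rf", "dt", "knn", "nb", "lda"))
    bad("unknown stage1_method: " %+% cfg$stage1_method)
  unknown <- setdiff(cfg$stage1_features, TD_FEATURE_NAMES)
  if (length(unknown)) bad("unknown stage1_features: " %+%
                             paste(unknown, collapse = ", "))
  if (cfg$val_fraction < 0 || cfg$val_fraction >= 1)
    bad("val_fraction must be in [0, 1)")
  invisible(cfg)
}

`%+%` <- function(a, b) paste0(a, b)

#' Load a run configuration from YAML
#'
#' Every key must be a field of [emg_config()]; unknown keys and invariant
#' violations raise a configuration error. An empty file yields all defaults.
#'
#' @param path Path to a YAML file (keys as in [emg_config()]).
#' @return An `emg_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.list(vals)) stop("config file must hold a YAML mapping", call. = FALSE)
  known <- names(formals(emg_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(vals$superclass_map))
    vals$superclass_map <- unlist(vals$superclass_map)
  do.call(emg_config, vals)
}
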