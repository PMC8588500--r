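#' Construct a multichannel sEMG recording
#'
#' The central container of the package: a samples-by-channels signal matrix
#' with a sampling rate and a per-sample integer label stream (0 = rest,
#' positive integers = gesture ids), as produced by acquisition hardware such
#' as the Ninapro electrode arrays or by [simulate_recording()].
#'
#' @param signal Numeric matrix, `n_samples x n_channels`.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param labels Integer vector of length `n_samples`; 0 means rest, values
#'   greater than 0 are gesture ids.
#' @param subject_id,exercise_id Opaque identifier strings.
#' @return An object of class `emg_recording`.
#' @examples
#' rec <- emg_recording(matrix(rnorm(300), 100, 3), fs = 100,
#'                      labels = rep(c(0L, 1L), each = 50))
#' dim(rec$signal)
#' @export
emg_recording <- function(signal, fs, labels = NULL,
                          subject_id = "unknown", exercise_id = "unknown") {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (is.null(labels)) labels <- integer(nrow(signal))
  labels <- as.integer(labels)
  rec <- structure(
    list(signal = signal, fs = as.numeric(fs), labels = labels,
         subject_id = as.character(subject_id),
         exercise_id = as.character(exercise_id)),
    class = "emg_recording")
  validate_recording(rec)
  rec
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, nrow(x$signal) / x$fs))
  active <- sum(x$labels > 0L)
  cat(sprintf("  subject %s, exercise %s; %d active samples (%.1f%%), %d gesture ids\n",
              x$subject_id, x$exercise_id, active,
              100 * active / length(x$labels),
              length(setdiff(unique(x$labels), 0L))))
  invisible(x)
}

validate_recording <- function(rec) {
  if (!is.matrix(rec$signal) || nrow(rec$signal) < 1L || ncol(rec$signal) < 1L)
    stop("recording signal must be a matrix with >= 1 sample and >= 1 channel",
         call. = FALSE)
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || is.na(rec$fs) || rec$fs <= 0)
    stop("sampling rate fs must be a positive scalar", call. = FALSE)
  if (length(rec$labels) != nrow(rec$signal))
    stop(sprintf("labels length (%d) must equal n_samples (%d)",
                 length(rec$labels), nrow(rec$signal)), call. = FALSE)
  if (anyNA(rec$labels) || any(rec$labels < 0L))
    stop("labels must be non-negative integers (0 = rest)", call. = FALSE)
  invisible(rec)
}

n_samples <- function(rec) nrow(rec$signal)
n_channels <- function(rec) ncol(rec$signal)

#' Gesture taxonomy: partition of gesture ids into superclasses
#'
#' Stage 1 of the framework predicts a coarse superclass (e.g. finger, wrist,
#' functional movements, which differ in typical force level); stage 2 holds
#' one classifier per superclass that resolves the exact gesture.
#'
#' @param superclass_map Named integer vector or list mapping gesture id
#'   (names, coercible to integer) to superclass id, or a two-column
#'   data.frame `gesture_id`, `superclass_id`.
#' @param superclass_names Optional character vector naming each superclass id.
#' @return An object of class `gesture_taxonomy` with elements `map` (named
#'   integer vector), `superclasses` (integer vector of distinct ids) and
#'   `members` (list of gesture ids per superclass).
#' @examples
#' tax <- gesture_taxonomy(c(`1` = 1, `2` = 1, `3` = 2, `4` = 2))
#' tax$members
#' @export
gesture_taxonomy <- function(superclass_map, superclass_names = NULL) {
  if (is.data.frame(superclass_map)) {
    map <- as.integer(superclass_map$superclass_id)
    names(map) <- as.character(as.integer(superclass_map$gesture_id))
  } else {
    map <- vapply(superclass_map, as.integer, integer(1))
    names(map) <- as.character(as.integer(names(superclass_map)))
  }
  if (anyNA(map) || is.null(names(map)) || anyDuplicated(names(map)))
    stop("superclass_map must map each gesture id to exactly one superclass",
         call. = FALSE)
  sc <- sort(unique(map))
  if (length(sc) < 2L)
    stop("a gesture taxonomy needs at least 2 superclasses", call. = FALSE)
  members <- lapply(sc, function(s) sort(as.integer(names(map)[map == s])))
  names(members) <- as.character(sc)
  structure(list(map = map, superclasses = sc, members = members,
                 superclass_names = superclass_names,
                 k = length(sc)),
            class = "gesture_taxonomy")
}

#' Look up the superclass of gesture ids
#' @param taxonomy A [gesture_taxonomy()].
#' @param gesture_ids Integer vector of gesture ids.
#' @return Integer vector of superclass ids.
#' @export
superclass_of <- function(taxonomy, gesture_ids) {
  out <- taxonomy$map[as.character(as.integer(gesture_ids))]
  if (anyNA(out))
    stop("gesture id(s) absent from taxonomy: ",
         paste(unique(gesture_ids[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}
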