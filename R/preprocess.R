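#' Per-channel Z-score normalization
#'
#' Standardizes every channel to zero mean and unit variance, the
#' normalization applied to the whole dataset before windowing.
#'
#' @param rec An [emg_recording()]; every channel must have nonzero variance.
#' @return The recording with standardized signal.
#' @export
zscore <- function(rec) {
  validate_recording(rec)
  sds <- apply(rec$signal, 2L, stats::sd)
  if (any(sds == 0 | is.na(sds)))
    stop("cannot z-score constant channel(s): ",
         paste(which(sds == 0 | is.na(sds)), collapse = ", "), call. = FALSE)
  rec$signal <- scale(rec$signal)[, , drop = FALSE]
  attr(rec$signal, "scaled:center") <- NULL
  attr(rec$signal, "scaled:scale") <- NULL
  rec
}

#' Discrete Teager-Kaiser energy operator
#'
#' `psi(n) = x(n)^2 - x(n-1) * x(n+1)` at interior samples; the two boundary
#' samples replicate the nearest interior value, so the output length equals
#' the input length. The operator tracks instantaneous amplitude-frequency
#' energy: for `A*cos(w*n)` it returns the constant `A^2 * sin(w)^2`.
#'
#' @param x Numeric vector, length >= 3.
#' @return Numeric vector of the same length.
#' @examples
#' teager_energy(c(0, 1, 2, 3, 4))  # unit ramp -> all ones
#' @export
teager_energy <- function(x) {
  n <- length(x)
  if (n < 3L) stop("teager_energy needs at least 3 samples", call. = FALSE)
  psi <- numeric(n)
  i <- 2L:(n - 1L)
  psi[i] <- x[i]^2 - x[i - 1L] * x[i + 1L]
  psi[1L] <- psi[2L]
  psi[n] <- psi[n - 1L]
  psi
}

#' Channel-averaged, time-smoothed Teager energy
#'
#' Per-sample Teager energy averaged across all channels, then passed
#' through a causal moving average of width `N` samples (the window ends at
#' the current sample and is shortened at the left edge).
#'
#' @param rec An [emg_recording()].
#' @param N Moving-average width in samples (>= 1, <= n_samples).
#' @return Numeric vector of length `n_samples`.
#' @export
smoothed_channel_energy <- function(rec, N) {
  validate_recording(rec)
  N <- as.integer(N)
  if (N < 1L) stop("smoothing width N must be >= 1", call. = FALSE)
  if (N > n_samples(rec))
    stop("smoothing width N exceeds the number of samples", call. = FALSE)
  e_avg <- rowMeans(apply(rec$signal, 2L, teager_energy))
  if (N == 1L) return(e_avg)
  cs <- cumsum(e_avg)
  n <- length(e_avg)
  out <- numeric(n)
  i <- seq_len(n)
  lo <- pmax(i - N, 0L)
  out <- (cs[i] - c(0, cs)[lo + 1L]) / (i - lo)
  out
}

#' Detect active segments by hard thresholding with duration hysteresis
#'
#' A segment opens at the first sample of a run of at least `min_dur`
#' supra-threshold samples and closes at the first sample of a run of at
#' least `min_dur` sub-threshold samples; detections shorter than `min_dur`
#' are discarded. Only threshold crossings and run lengths matter, not the
#' energy values between crossings.
#'
#' @param energy Smoothed energy vector (see [smoothed_channel_energy()]).
#' @param threshold Positive hard threshold.
#' @param min_dur Minimum run length in samples (>= 1).
#' @return An `activity_intervals` object: data.frame `intervals` with
#'   0-based half-open `start_sample`/`end_sample`, plus the threshold and
#'   smoothing metadata used.
#' @export
detect_active <- function(energy, threshold, min_dur = 1L, smooth_N = NA_integer_) {
  stopifnot(threshold > 0, min_dur >= 1L)
  min_dur <- as.integer(min_dur)
  above <- energy > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts0 <- c(0L, ends[-length(ends)])  # 0-based run starts
  open_at <- NA_integer_
  iv <- list()
  for (j in seq_along(r$lengths)) {
    long_run <- r$lengths[j] >= min_dur
    if (is.na(open_at) && r$values[j] && long_run) {
      open_at <- starts0[j]
    } else if (!is.na(open_at) && !r$values[j] && long_run) {
      iv[[length(iv) + 1L]] <- c(open_at, starts0[j])
      open_at <- NA_integer_
    }
  }
  if (!is.na(open_at)) iv[[length(iv) + 1L]] <- c(open_at, length(energy))
  iv <- do.call(rbind, iv)
  intervals <- if (is.null(iv))
    data.frame(start_sample = integer(0), end_sample = integer(0))
  else
    data.frame(start_sample = as.integer(iv[, 1L]),
               end_sample = as.integer(iv[, 2L]))
  intervals <- intervals[intervals$end_sample - intervals$start_sample >= min_dur, ,
                         drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(intervals = intervals, threshold_used = threshold,
                 smooth_N = smooth_N), class = "activity_intervals")
}

#' Automatic energy threshold from the rest baseline
#'
#' Estimates the rest-level energy as the 10th percentile of the smoothed
#' energy stream and places the threshold a fixed multiple (5x) above it.
#' The multiplicative margin tracks the scale of the rest noise, which an
#' additive few-SD margin over the quietest samples does not: the lowest
#' decile systematically underestimates rest variability and puts an
#' additive threshold inside the rest fluctuation band.
#'
#' @param energy Smoothed energy vector.
#' @param margin Multiple of the rest-level estimate (default 5).
#' @return Positive threshold.
#' @export
auto_threshold <- function(energy, margin = 5) {
  thr <- margin * stats::quantile(energy, 0.1, names = FALSE)
  if (!is.finite(thr) || thr <= 0) thr <- .Machine$double.eps
  thr
}

#' Locate activity and relabel a recording with the Teager-energy detector
#'
#' Convenience wrapper: smoothed channel energy -> threshold (automatic
#' unless configured) -> [detect_active()] -> [relabel()].
#'
#' @param rec An [emg_recording()].
#' @param config An [emg_config()].
#' @return List with elements `recording` (relabeled) and `intervals`.
#' @export
teager_relabel <- function(rec, config = emg_config()) {
  N <- config$teager_smooth_N
  if (is.null(N)) N <- max(1L, round(0.1 * rec$fs))
  energy <- smoothed_channel_energy(rec, N)
  thr <- config$teager_threshold
  if (is.null(thr)) thr <- auto_threshold(energy)
  min_dur <- max(1L, round(config$min_active_ms * rec$fs / 1000))
  acts <- detect_active(energy, thr, min_dur, smooth_N = N)
  list(recording = relabel(rec, acts), intervals = acts)
}

#' Replace the label stream using detected activity intervals
#'
#' Samples inside each interval receive the majority gesture id of the
#' original labels overlapping that interval; samples outside all intervals
#' become rest (0). When an interval overlaps no nonzero original label, it
#' borrows the label of the nearest labeled interval, with a warning.
#'
#' @param rec An [emg_recording()].
#' @param intervals An `activity_intervals` object (or its data.frame).
#' @return The recording with the replaced label stream.
#' @export
relabel <- function(rec, intervals) {
  validate_recording(rec)
  iv <- if (inherits(intervals, "activity_intervals")) intervals$intervals
        else as.data.frame(intervals)
  n <- n_samples(rec)
  if (nrow(iv) && (min(iv$start_sample) < 0L || max(iv$end_sample) > n))
    stop("intervals out of recording bounds", call. = FALSE)
  new_labels <- integer(n)
  assigned <- rep(NA_integer_, nrow(iv))
  for (j in seq_len(nrow(iv))) {
    idx <- (iv$start_sample[j] + 1L):iv$end_sample[j]
    overl <- rec$labels[idx]
    overl <- overl[overl > 0L]
    if (length(overl)) {
      tab <- table(overl)
      assigned[j] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  if (anyNA(assigned) && any(!is.na(assigned))) {
    warning("interval(s) overlapping no labeled samples; ",
            "borrowing the nearest labeled interval's gesture id")
    centers <- (iv$start_sample + iv$end_sample) / 2
    for (j in which(is.na(assigned))) {
      src <- which(!is.na(assigned))
      assigned[j] <- assigned[src[which.min(abs(centers[src] - centers[j]))]]
    }
  }
  for (j in seq_len(nrow(iv))) {
    if (is.na(assigned[j])) next
    new_labels[(iv$start_sample[j] + 1L):iv$end_sample[j]] <- assigned[j]
  }
  rec$labels <- new_labels
  rec
}

#' Cut fixed-length non-overlapping windows from labeled runs
#'
#' Windows are cut only inside runs of identical nonzero label, restarting
#' at every run boundary, so no window ever straddles two labels; trailing
#' partial windows are dropped. Each window carries the run's gesture id
#' and, when a taxonomy is supplied, its superclass.
#'
#' @param rec An [emg_recording()].
#' @param window_ms Window length in milliseconds.
#' @param taxonomy Optional [gesture_taxonomy()] for the superclass field.
#' @return List of `segment_window` objects (fields `data`, `label`,
#'   `superclass`, `start_sample`).
#' @export
segment_windows <- function(rec, window_ms = 400, taxonomy = NULL) {
  validate_recording(rec)
  wlen <- round(window_ms * rec$fs / 1000)
  if (wlen < 1L) stop("window shorter than one sample", call. = FALSE)
  r <- rle(rec$labels)
  run_end <- cumsum(r$lengths)
  run_start0 <- c(0L, run_end[-length(run_end)])
  out <- list()
  for (j in seq_along(r$lengths)) {
    if (r$values[j] == 0L) next
    n_win <- r$lengths[j] %/% wlen
    if (n_win < 1L) next
    sc <- if (is.null(taxonomy)) NA_integer_
          else superclass_of(taxonomy, r$values[j])
    for (w in seq_len(n_win)) {
      s0 <- run_start0[j] + (w - 1L) * wlen
      out[[length(out) + 1L]] <- structure(
        list(data = rec$signal[(s0 + 1L):(s0 + wlen), , drop = FALSE],
             label = r$values[j], superclass = sc,
             start_sample = as.integer(s0)),
        class = "segment_window")
    }
  }
  out
}
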