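#' Read a Ninapro-style MAT-file as a recording
#'
#' Maps a Ninapro DB1 subject file (10 electrode channels sampled at 100 Hz,
#' 52 gestures) onto an [emg_recording()]. Field names are resolved
#' case-insensitively through `field_map`; by default the signal is taken
#' from `emg` and the per-sample label stream from `stimulus` (fall back to
#' `restimulus` when `stimulus` is absent).
#'
#' @param path Path to the MAT-file (MATLAB v5).
#' @param fs Sampling rate to record (Hz); DB1 is 100 Hz.
#' @param field_map Named list with entries `signal` and `labels` giving
#'   acceptable field names in priority order.
#' @return An [emg_recording()].
#' @export
read_ninapro_mat <- function(path, fs = 100,
                             field_map = list(
                               signal = "emg",
                               labels = c("stimulus", "restimulus"))) {
  vars <- read_mat5(path)
  names(vars) <- tolower(names(vars))
  pick <- function(cands, what) {
    hit <- intersect(tolower(cands), names(vars))
    if (!length(hit))
      stop(sprintf("MAT-file format error: no %s field (looked for: %s)",
                   what, paste(cands, collapse = ", ")), call. = FALSE)
    vars[[hit[1L]]]
  }
  signal <- as.matrix(pick(field_map$signal, "signal"))
  labels <- as.vector(pick(field_map$labels, "label"))
  if (length(labels) != nrow(signal))
    stop(sprintf(paste0("MAT-file integrity error: label length (%d) does ",
                        "not match signal samples (%d)"),
                 length(labels), nrow(signal)), call. = FALSE)
  subject <- if (!is.null(vars$subject)) as.character(vars$subject[1L]) else "unknown"
  exercise <- if (!is.null(vars$exercise)) as.character(vars$exercise[1L]) else "unknown"
  emg_recording(signal, fs = fs, labels = as.integer(round(labels)),
                subject_id = subject, exercise_id = exercise)
}

#' Write / read a recording as HDF5
#'
#' The package's interchange format for signals: datasets `/signal`
#' (samples x channels) and `/labels`, with `fs`, `subject_id` and
#' `exercise_id` stored as attributes of `/signal`.
#'
#' @param rec An [emg_recording()].
#' @param path Output `.h5` path (overwritten if present).
#' @return Invisibly, `path` (for `write_recording`); an `emg_recording`
#'   (for `read_recording`).
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) stop("cannot create HDF5 file: ", path, call. = FALSE)
  rhdf5::h5write(rec$signal, path, "signal")
  rhdf5::h5write(rec$labels, path, "labels")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "signal")
  rhdf5::h5writeAttribute(rec$fs, did, "fs")
  rhdf5::h5writeAttribute(rec$subject_id, did, "subject_id")
  rhdf5::h5writeAttribute(rec$exercise_id, did, "exercise_id")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  signal <- rhdf5::h5read(path, "signal")
  labels <- as.integer(rhdf5::h5read(path, "labels"))
  at <- rhdf5::h5readAttributes(path, "signal")
  emg_recording(signal, fs = as.numeric(at$fs), labels = labels,
                subject_id = if (is.null(at$subject_id)) "unknown" else at$subject_id,
                exercise_id = if (is.null(at$exercise_id)) "unknown" else at$exercise_id)
}

#' Write / read a mode tensor as HDF5
#'
#' Datasets `/modes` (K x samples x channels), `/center_freqs`, `/residual`;
#' the decomposition settings go into attributes of `/modes`.
#'
#' @param mt A `mode_tensor` from [mvmd_decompose()].
#' @param path Output `.h5` path.
#' @export
write_modes <- function(mt, path) {
  stopifnot(inherits(mt, "mode_tensor"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(mt$modes, path, "modes")
  rhdf5::h5write(mt$center_freqs, path, "center_freqs")
  rhdf5::h5write(mt$residual, path, "residual")
  fid <- rhdf5::H5Fopen(path)
  did <- rhdf5::H5Dopen(fid, "modes")
  rhdf5::h5writeAttribute(mt$fs, did, "fs")
  rhdf5::h5writeAttribute(as.integer(mt$n_iterations), did, "n_iterations")
  rhdf5::h5writeAttribute(as.integer(mt$converged), did, "converged")
  rhdf5::H5Dclose(did)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname write_modes
#' @export
read_modes <- function(path) {
  modes <- rhdf5::h5read(path, "modes")
  at <- rhdf5::h5readAttributes(path, "modes")
  structure(list(
    modes = modes,
    center_freqs = as.numeric(rhdf5::h5read(path, "center_freqs")),
    residual = rhdf5::h5read(path, "residual"),
    fs = as.numeric(at$fs),
    n_iterations = as.integer(at$n_iterations),
    converged = as.logical(at$converged)), class = "mode_tensor")
}

#' Write a feature table as CSV
#'
#' Columns: `window_id`, `start_sample`, `label`, `superclass`, then one
#' `ch<c>_<FEAT>` column per channel and feature.
#'
#' @param feats Feature data.frame from [extract_feature_table()].
#' @param path Output `.csv` path.
#' @export
write_feature_table <- function(feats, path) {
  data.table::fwrite(feats, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  as.data.frame(data.table::fread(path))
}
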