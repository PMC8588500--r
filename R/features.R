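# The eight classical time-domain features used for superclass routing.
# Formulas follow the common EMG definitions used in this framework exactly,
# including VAR as a raw (uncentered) sum of squares over L-1.

TD_FEATURE_NAMES <- c("RMS", "MAV", "WL", "ZC", "SSC", "DASDV", "WA", "VAR")

check_len <- function(x, min_len, op) {
  if (length(x) < min_len)
    stop(op, " needs at least ", min_len, " samples", call. = FALSE)
}

#' Time-domain EMG features
#'
#' Scalar features of a single-channel window `x` of length `L`:
#' * `rms(x)`: root mean square, `sqrt(sum(x^2) / L)`.
#' * `mav(x)`: mean absolute value, `sum(|x|) / L`.
#' * `wl(x)`: wavelength (waveform length), `sum_{i=2..L} |x_i - x_{i-1}|`.
#' * `var_raw(x)`: raw variance `sum(x^2) / (L - 1)` — no mean subtraction
#'   (set `centered = TRUE` for the conventional variance).
#' * `dasdv(x)`: difference absolute standard deviation value,
#'   `sqrt(sum((x_{i+1} - x_i)^2) / (L - 1))`.
#' * `zc(x, T)`: zero crossings — adjacent pairs with opposite sign and
#'   amplitude gap above the dead-band `T`.
#' * `ssc(x, T)`: slope sign changes — interior strict local extrema whose
#'   gaps to both neighbours are at least `T`.
#' * `wa(x, T)`: Willison amplitude — adjacent gaps exceeding `T`.
#'
#' @param x Numeric vector (length >= 2; `ssc` needs >= 3).
#' @param T Non-negative amplitude dead-band for the count features.
#' @param centered For `var_raw`, subtract the mean first (off by default).
#' @return A scalar (counts are non-negative integers, at most `L - 1`).
#' @name td_features
NULL

#' @rdname td_features
#' @export
rms <- function(x) { check_len(x, 2L, "rms"); sqrt(sum(x^2) / length(x)) }

#' @rdname td_features
#' @export
mav <- function(x) { check_len(x, 2L, "mav"); sum(abs(x)) / length(x) }

#' @rdname td_features
#' @export
wl <- function(x) { check_len(x, 2L, "wl"); sum(abs(diff(x))) }

#' @rdname td_features
#' @export
var_raw <- function(x, centered = FALSE) {
  check_len(x, 2L, "var_raw")
  if (centered) x <- x - mean(x)
  sum(x^2) / (length(x) - 1L)
}

#' @rdname td_features
#' @export
dasdv <- function(x) {
  check_len(x, 2L, "dasdv")
  sqrt(sum(diff(x)^2) / (length(x) - 1L))
}

#' @rdname td_features
#' @export
zc <- function(x, T = 0) {
  check_len(x, 2L, "zc")
  stopifnot(T >= 0)
  a <- x[-length(x)]; b <- x[-1L]
  sum(a * b < 0 & abs(a - b) > T)
}

#' @rdname td_features
#' @export
ssc <- function(x, T = 0) {
  check_len(x, 3L, "ssc")
  stopifnot(T >= 0)
  i <- 2L:(length(x) - 1L)
  xm <- x[i]; xl <- x[i - 1L]; xr <- x[i + 1L]
  extremum <- (xm > xl & xm > xr) | (xm < xl & xm < xr)
  sum(extremum & abs(xm - xl) >= T & abs(xm - xr) >= T)
}

#' @rdname td_features
#' @export
wa <- function(x, T = 0) {
  check_len(x, 2L, "wa")
  stopifnot(T >= 0)
  sum(abs(diff(x)) > T)
}

td_feature_fun <- function(name, T) {
  switch(name,
         RMS = rms, MAV = mav, WL = wl, VAR = var_raw, DASDV = dasdv,
         ZC = function(x) zc(x, T),
         SSC = function(x) ssc(x, T),
         WA = function(x) wa(x, T),
         stop("unknown feature name: ", name, call. = FALSE))
}

#' Extract time-domain features from a window
#'
#' Computes the selected features per channel and concatenates them
#' channel-major (all features of channel 1, then channel 2, ...), carrying
#' the window's gesture label and superclass.
#'
#' @param win A `segment_window` from [segment_windows()], or a numeric
#'   matrix (samples x channels).
#' @param selected Feature names, a subset of
#'   `RMS, MAV, WL, ZC, SSC, DASDV, WA, VAR`.
#' @param T Dead-band threshold for the count features (`ZC`/`SSC`/`WA`).
#' @return A `feature_vector`: `values` (named numeric vector of length
#'   `n_channels * length(selected)`), `feature_names`, `label`, `superclass`,
#'   `start_sample`.
#' @export
extract_features <- function(win, selected = c("RMS", "MAV", "DASDV"),
                             T = 0.01) {
  unknown <- setdiff(selected, TD_FEATURE_NAMES)
  if (length(unknown))
    stop("unknown feature name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  data <- if (inherits(win, "segment_window")) win$data else as.matrix(win)
  C <- ncol(data)
  vals <- numeric(0)
  for (ch in seq_len(C)) {
    for (f in selected) {
      vals <- c(vals, td_feature_fun(f, T)(data[, ch]))
    }
  }
  names(vals) <- as.vector(t(outer(seq_len(C), selected,
                                   function(c, f) sprintf("ch%d_%s", c, f))))
  structure(list(values = vals, feature_names = selected,
                 label = if (inherits(win, "segment_window")) win$label else NA_integer_,
                 superclass = if (inherits(win, "segment_window")) win$superclass else NA_integer_,
                 start_sample = if (inherits(win, "segment_window")) win$start_sample else NA_integer_),
            class = "feature_vector")
}

#' Build a feature table for a list of windows
#'
#' @param windows List of `segment_window`s.
#' @param selected,T As in [extract_features()].
#' @return data.frame: `window_id`, `start_sample`, `label`, `superclass`,
#'   then one `ch<c>_<FEAT>` column per channel and feature.
#' @export
extract_feature_table <- function(windows, selected = c("RMS", "MAV", "DASDV"),
                                  T = 0.01) {
  stopifnot(length(windows) > 0L)
  fvs <- lapply(windows, extract_features, selected = selected, T = T)
  mat <- do.call(rbind, lapply(fvs, `[[`, "values"))
  data.frame(window_id = seq_along(windows),
             start_sample = vapply(fvs, `[[`, integer(1), "start_sample"),
             label = vapply(fvs, `[[`, integer(1), "label"),
             superclass = vapply(fvs, `[[`, integer(1), "superclass"),
             mat, check.names = FALSE)
}
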