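# Minimal MATLAB Level-5 MAT-file support: numeric (real, non-sparse) arrays
# only, which covers Ninapro-style recordings (emg/stimulus/restimulus/...).
# Handles little- and big-endian files, small-data-element tags, and
# zlib-compressed (miCOMPRESSED) elements.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L; MI_UTF8 <- 16L

MX_NUMERIC_CLASSES <- c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L)

#' Read a MATLAB v5 MAT-file of numeric arrays
#'
#' A self-contained reader for the Level-5 MAT format restricted to what
#' biosignal datasets actually ship: real, dense numeric matrices (including
#' zlib-compressed elements). Cell arrays, structs, sparse and complex
#' matrices are rejected with an informative error.
#'
#' @param path Path to a `.mat` file.
#' @return Named list of numeric matrices/vectors (column-major, as stored).
#' @seealso [read_ninapro_mat()] for mapping a Ninapro file onto an
#'   [emg_recording()].
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 128L) stop("not a MAT v5 file (truncated header): ", path,
                               call. = FALSE)
  endmark <- rawToChar(raw[127:128])
  endian <- if (endmark == "IM") "little" else if (endmark == "MI") "big" else
    stop("not a MAT v5 file (bad endian indicator): ", path, call. = FALSE)
  out <- list()
  pos <- 129L
  while (pos <= length(raw)) {
    el <- mat5_read_element(raw, pos, endian)
    pos <- el$next_pos
    if (el$type == MI_COMPRESSED) {
      payload <- memDecompress(el$data, type = "gzip")
      sub <- mat5_read_element(payload, 1L, endian)
      if (sub$type == MI_MATRIX) {
        v <- mat5_parse_matrix(sub$data, endian)
        if (!is.null(v)) out[[v$name]] <- v$value
      }
    } else if (el$type == MI_MATRIX) {
      v <- mat5_parse_matrix(el$data, endian)
      if (!is.null(v)) out[[v$name]] <- v$value
    }
  }
  out
}

# One tagged data element starting at pos; returns type, raw payload, next pos.
mat5_read_element <- function(raw, pos, endian) {
  word1 <- mat5_uint32(raw[pos:(pos + 3L)], endian)
  small <- word1 > 65535
  if (small) {
    type <- word1 %% 65536
    nbytes <- word1 %/% 65536
    data <- raw[(pos + 4L):(pos + 3L + nbytes)]
    if (nbytes == 0L) data <- raw[0]
    list(type = as.integer(type), data = data, next_pos = pos + 8L)
  } else {
    nbytes <- mat5_uint32(raw[(pos + 4L):(pos + 7L)], endian)
    data <- if (nbytes > 0) raw[(pos + 8L):(pos + 7L + nbytes)] else raw[0]
    # compressed elements are not padded to the 8-byte boundary
    pad <- if (word1 == MI_COMPRESSED) 0L else (8L - nbytes %% 8L) %% 8L
    list(type = as.integer(word1), data = data,
         next_pos = pos + 8L + as.integer(nbytes) + pad)
  }
}

mat5_uint32 <- function(b, endian) {
  x <- readBin(b, "integer", n = 1L, size = 4L, endian = endian)
  if (x < 0) x + 4294967296 else as.numeric(x)
}

# Payload of a miMATRIX element -> list(name, value) or NULL if unsupported.
mat5_parse_matrix <- function(raw, endian) {
  flags <- mat5_read_element(raw, 1L, endian)
  fw <- mat5_uint32(flags$data[1:4], endian)
  class_id <- as.integer(fw %% 256)
  is_complex <- as.integer((fw %/% 2048) %% 2) == 1L  # bit 11
  dims_el <- mat5_read_element(raw, flags$next_pos, endian)
  dims <- readBin(dims_el$data, "integer", n = length(dims_el$data) %/% 4L,
                  size = 4L, endian = endian)
  name_el <- mat5_read_element(raw, dims_el$next_pos, endian)
  name <- rawToChar(name_el$data)
  if (!class_id %in% MX_NUMERIC_CLASSES) return(NULL)  # cell/struct/char/...
  if (is_complex)
    stop("unsupported MAT content: complex array '", name, "'", call. = FALSE)
  data_el <- mat5_read_element(raw, name_el$next_pos, endian)
  vals <- mat5_decode_numeric(data_el$data, data_el$type, endian, name)
  n <- prod(dims)
  if (length(vals) < n)
    stop("MAT integrity error: array '", name, "' shorter than its dimensions",
         call. = FALSE)
  list(name = name,
       value = array(as.numeric(vals[seq_len(n)]), dim = dims))
}

mat5_decode_numeric <- function(b, type, endian, name) {
  rd <- function(size, signed = TRUE, what = "integer")
    readBin(b, what, n = length(b) %/% size, size = size, signed = signed,
            endian = endian)
  switch(as.character(type),
    "1" = rd(1L),
    "2" = rd(1L, signed = FALSE),
    "3" = rd(2L),
    "4" = rd(2L, signed = FALSE),
    "5" = rd(4L),
    "6" = {x <- rd(4L); x + ifelse(x < 0, 4294967296, 0)},
    "7" = rd(4L, what = "double"),
    "9" = rd(8L, what = "double"),
    stop("unsupported MAT data type ", type, " in array '", name, "'",
         call. = FALSE))
}

# Minimal writer (real double matrices), used to build fixtures and for
# interoperability smoke tests. Always little-endian.
#' Write numeric matrices to a MATLAB v5 MAT-file
#' @param vars Named list of numeric vectors/matrices.
#' @param path Output path.
#' @param compress Write each variable as a zlib-compressed element.
#' @return Invisibly, `path`.
#' @export
write_mat5 <- function(vars, path, compress = FALSE) {
  stopifnot(is.list(vars), length(names(vars)) == length(vars))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("MATLAB 5.0 MAT-file, written by emgflow%s",
                              strrep(" ", 200)))[1:116]
  writeBin(header, con)
  writeBin(raw(8L), con)                       # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)         # version 0x0100 (little-endian)
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) {
    el <- mat5_encode_matrix(nm, vars[[nm]])
    if (compress) {
      # the compressed stream holds the complete element, tag included
      z <- memCompress(c(mat5_tag(MI_MATRIX, length(el)), el), type = "gzip")
      writeBin(c(mat5_tag(MI_COMPRESSED, length(z)), z), con)
    } else {
      writeBin(c(mat5_tag(MI_MATRIX, length(el)), el), con)
    }
  }
  invisible(path)
}

mat5_tag <- function(type, nbytes)
  writeBin(as.integer(c(type, nbytes)), raw(), size = 4L, endian = "little")

mat5_pad8 <- function(b) c(b, raw((8L - length(b) %% 8L) %% 8L))

mat5_encode_matrix <- function(name, value) {
  m <- as.matrix(value)
  storage.mode(m) <- "double"
  flags <- c(mat5_tag(MI_UINT32, 8L),
             writeBin(c(6L, 0L), raw(), size = 4L, endian = "little"))
  dims <- c(mat5_tag(MI_INT32, 8L),
            writeBin(as.integer(dim(m)), raw(), size = 4L, endian = "little"))
  nm_raw <- charToRaw(name)
  nm <- mat5_pad8(c(mat5_tag(MI_INT8, length(nm_raw)), nm_raw))
  dat <- c(mat5_tag(MI_DOUBLE, 8L * length(m)),
           writeBin(as.vector(m), raw(), size = 8L, endian = "little"))
  c(flags, dims, nm, mat5_pad8(dat))
}
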