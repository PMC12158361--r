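# Minimal MAT v5 (Level 5 MAT-file) reader/writer.  No MAT binding ships with
# this R stack, so the subset needed for Ninapro-style files is implemented
# here: numeric (real) matrices, little-endian, with support for normal and
# small data-element tags and for zlib-compressed elements (what scipy.io and
# MATLAB -v5/-v7 write).

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L

mi_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L, `6` = 4L,
             `7` = 4L, `9` = 8L, `12` = 8L, `13` = 8L)

read_mi_values <- function(raw, type, nbytes) {
  sz <- mi_size[[as.character(type)]]
  n <- nbytes %/% sz
  switch(as.character(type),
    `1` = readBin(raw, "integer", n, 1L, signed = TRUE, endian = "little"),
    `2` = readBin(raw, "integer", n, 1L, signed = FALSE, endian = "little"),
    `3` = readBin(raw, "integer", n, 2L, signed = TRUE, endian = "little"),
    `4` = readBin(raw, "integer", n, 2L, signed = FALSE, endian = "little"),
    `5` = readBin(raw, "integer", n, 4L, endian = "little"),
    `6` = readBin(raw, "integer", n, 4L, endian = "little"),
    `7` = readBin(raw, "double", n, 4L, endian = "little"),
    `9` = readBin(raw, "double", n, 8L, endian = "little"),
    `12` = readBin(raw, "double", n, 8L, endian = "little"),
    `13` = readBin(raw, "double", n, 8L, endian = "little"),
    abort(sprintf("Unsupported MAT data type %d.", type))
  )
}

# read one data element (tag + payload) starting at offset `pos` (1-based);
# returns list(type, payload raw, next_pos)
read_element <- function(buf, pos) {
  word1 <- readBin(buf[pos + 0:3], "integer", 1, 4L, endian = "little")
  small_len <- bitwAnd(bitwShiftR(word1, 16L), 0xFFFFL)
  if (small_len > 0L) {          # small data element: tag and data in 8 bytes
    type <- bitwAnd(word1, 0xFFFFL)
    payload <- buf[pos + 4:(4 + small_len - 1)]
    return(list(type = type, payload = payload, next_pos = pos + 8L))
  }
  type <- word1
  nbytes <- readBin(buf[pos + 4:7], "integer", 1, 4L, endian = "little")
  payload <- if (nbytes > 0L) buf[pos + 8L + seq_len(nbytes) - 1L] else raw(0)
  pad <- (8L - nbytes %% 8L) %% 8L
  list(type = type, payload = payload, next_pos = pos + 8L + nbytes + pad)
}

# parse one miMATRIX payload into list(name, value)
parse_matrix_element <- function(payload) {
  el <- read_element(payload, 1L)            # array flags
  flags <- readBin(el$payload[1:4], "integer", 1, 4L, endian = "little")
  klass <- bitwAnd(flags, 0xFFL)
  el2 <- read_element(payload, el$next_pos)  # dimensions
  dims <- read_mi_values(el2$payload, MI_INT32, length(el2$payload))
  el3 <- read_element(payload, el2$next_pos) # name
  name <- rawToChar(el3$payload[el3$payload != as.raw(0)])
  if (!klass %in% c(6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L)) {
    return(list(name = name, value = NULL))  # non-numeric class: skip
  }
  el4 <- read_element(payload, el3$next_pos) # real part
  vals <- read_mi_values(el4$payload, el4$type, length(el4$payload))
  value <- array(as.double(vals), dim = dims)
  if (length(dims) == 2L) value <- matrix(value, dims[1], dims[2])
  list(name = name, value = value)
}

#' Read a MAT v5 file of numeric arrays
#'
#' Supports little-endian Level 5 MAT-files holding real numeric matrices,
#' including zlib-compressed variables.  Non-numeric variables are skipped.
#'
#' @param path Path to a `.mat` file.
#' @return A named list of numeric matrices/arrays.
#' @export
read_mat5 <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("MAT file not found: %s", path), class = "semg_io_error")
  }
  buf <- readBin(path, "raw", file.info(path)$size)
  if (length(buf) < 128L) {
    abort(sprintf("Not a MAT v5 file (too short): %s", path),
          class = "semg_io_error")
  }
  endian <- rawToChar(buf[127:128])
  if (endian != "IM") {
    abort(sprintf("Unsupported MAT endianness marker '%s' in %s.",
                  endian, path), class = "semg_io_error")
  }
  out <- list()
  pos <- 129L
  while (pos + 7L <= length(buf)) {
    el <- read_element(buf, pos)
    payload <- el$payload
    type <- el$type
    if (type == MI_COMPRESSED) {
      payload <- memDecompress(payload, type = "gzip")
      inner <- read_element(payload, 1L)
      type <- inner$type
      payload <- inner$payload
    }
    if (type == MI_MATRIX) {
      var <- parse_matrix_element(payload)
      if (!is.null(var$value)) out[[var$name]] <- var$value
    }
    pos <- el$next_pos
  }
  out
}

write_tag <- function(con, type, nbytes) {
  writeBin(as.integer(c(type, nbytes)), con, 4L, endian = "little")
}

write_padded <- function(con, bytes) {
  writeBin(bytes, con)
  pad <- (8L - length(bytes) %% 8L) %% 8L
  if (pad) writeBin(raw(pad), con)
}

#' Write numeric matrices to a MAT v5 file
#'
#' Writes each element of a named list as an uncompressed double-precision
#' real matrix, readable by MATLAB, scipy.io and [read_mat5()].
#'
#' @param vars Named list of numeric vectors/matrices (vectors are written
#'   as column vectors).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mat5 <- function(vars, path) {
  if (is.null(names(vars)) || any(names(vars) == "")) {
    abort("All variables must be named.")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header <- sprintf("MATLAB 5.0 MAT-file, created by semgimage on %s",
                    format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  hraw <- charToRaw(header)
  writeBin(c(hraw, rep(as.raw(0x20), 124L - length(hraw))), con)
  writeBin(as.raw(c(0x00, 0x01)), con)       # version 0x0100
  writeBin(charToRaw("IM"), con)             # little-endian marker
  for (nm in names(vars)) {
    m <- vars[[nm]]
    if (is.vector(m)) m <- matrix(m, ncol = 1L)
    storage.mode(m) <- "double"
    nraw <- charToRaw(nm)
    name_bytes <- 8L + length(nraw) + (8L - length(nraw) %% 8L) %% 8L
    data_bytes <- 8L + 8L * length(m)
    total <- 16L + 16L + name_bytes + data_bytes
    write_tag(con, MI_MATRIX, total)
    write_tag(con, MI_UINT32, 8L)            # array flags
    writeBin(as.integer(c(6L, 0L)), con, 4L, endian = "little")
    write_tag(con, MI_INT32, 8L)             # dimensions
    writeBin(as.integer(dim(m)), con, 4L, endian = "little")
    write_tag(con, MI_INT8, length(nraw))    # name
    write_padded(con, nraw)
    write_tag(con, MI_DOUBLE, 8L * length(m))
    writeBin(as.vector(m), con, 8L, endian = "little")
  }
  invisible(path)
}

#' Load a Ninapro-style recording from a MAT file
#'
#' Expects an `emg` matrix (samples x channels) and optionally `stimulus`,
#' `repetition` and `subject` variables; scalars or constant vectors are
#' accepted for the labels.  Explicit arguments override file contents,
#' which is how pre-segmented files whose provenance lives in the filename
#' (see [discover_recordings()]) are loaded.
#'
#' @param path Path to a `.mat` file.
#' @param subject,stimulus,repetition Optional label overrides.
#' @param fs Sampling rate in Hz (Ninapro DB1 is 100 Hz).
#' @return An [semg_recording()].
#' @export
read_ninapro_mat <- function(path, subject = NULL, stimulus = NULL,
                             repetition = NULL, fs = 100) {
  vars <- read_mat5(path)
  if (is.null(vars$emg)) {
    abort(sprintf("No `emg` variable in %s.", path), class = "semg_io_error")
  }
  label_of <- function(override, key) {
    if (!is.null(override)) return(as.integer(override))
    v <- vars[[key]]
    if (is.null(v)) return(NA_integer_)
    u <- unique(as.integer(round(v)))
    u <- u[u != 0L]
    if (length(u) == 0L) 0L else u[1L]
  }
  semg_recording(
    vars$emg, fs = fs,
    subject = {
      s <- label_of(subject, "subject")
      if (is.na(s)) 1L else s
    },
    stimulus = {
      s <- label_of(stimulus, "stimulus")
      if (is.na(s)) 0L else s
    },
    repetition = {
      r <- label_of(repetition, "repetition")
      if (is.na(r)) 1L else r
    }
  )
}

#' Read a raw arm-band CSV export
#'
#' One row per sample, one column per channel, optional header row.  The
#' 8-channel 500 Hz arm-band format is the default; any column count works.
#'
#' @param path Path to the CSV file.
#' @param fs Sampling rate in Hz (default 500).
#' @param subject,stimulus,repetition Provenance labels for the recording.
#' @return An [semg_recording()].
#' @export
read_armband_csv <- function(path, fs = 500, subject = 1L, stimulus = 0L,
                             repetition = 1L) {
  if (!file.exists(path)) {
    abort(sprintf("CSV file not found: %s", path), class = "semg_io_error")
  }
  first <- readLines(path, n = 1L)
  has_header <- !grepl("^[-+0-9.eE, \t;]*$", first)
  df <- readr::read_csv(path, col_names = has_header, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_double()))
  semg_recording(as.matrix(df), fs = fs, subject = subject,
                 stimulus = stimulus, repetition = repetition)
}
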