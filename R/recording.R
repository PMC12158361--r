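#' Construct an sEMG recording
#'
#' A recording is the unit of raw input: a samples-by-channels matrix of
#' (typically RMS-envelope) sEMG amplitudes at a fixed sampling rate, tagged
#' with the subject, gesture (stimulus) and repetition it came from.
#'
#' @param signal Numeric matrix, rows = time samples, columns = channels.
#'   A vector is treated as a single channel.
#' @param fs Sampling rate in Hz (> 0).
#' @param subject Positive integer subject id.
#' @param stimulus Non-negative integer gesture label (0 is conventionally
#'   rest).
#' @param repetition Positive integer repetition index.
#'
#' @return An object of class `semg_recording`.
#' @examples
#' rec <- semg_recording(matrix(abs(rnorm(200)), 100, 2), fs = 100,
#'                       subject = 1, stimulus = 3, repetition = 2)
#' rec
#' @export
semg_recording <- function(signal, fs, subject = 1L, stimulus = 0L,
                           repetition = 1L) {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1L)
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  if (ncol(signal) < 1L) abort("`signal` must have at least one channel.")
  if (anyNA(signal)) abort("`signal` must not contain missing values.")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  structure(
    list(signal = signal, fs = as.numeric(fs),
         subject = as.integer(subject), stimulus = as.integer(stimulus),
         repetition = as.integer(repetition)),
    class = "semg_recording"
  )
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf(
    "<semg_recording> %d samples x %d channels @ %g Hz (%.2f s)\n",
    nrow(x$signal), ncol(x$signal), x$fs, nrow(x$signal) / x$fs))
  cat(sprintf("  subject %d, stimulus %d, repetition %d\n",
              x$subject, x$stimulus, x$repetition))
  invisible(x)
}

#' @export
dim.semg_recording <- function(x) dim(x$signal)

is_recording <- function(x) inherits(x, "semg_recording")

assert_recording <- function(x) {
  if (!is_recording(x)) abort("Expected an `semg_recording` object.")
  invisible(x)
}
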