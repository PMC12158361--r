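#' Repetition-wise train/test split specification
#'
#' Ninapro DB1's standard protocol holds out repetitions 2 and 7 of every
#' movement for testing and trains on the remaining eight, a 4:1 split that
#' keeps all windows of one movement execution on the same side of the
#' partition.
#'
#' @param train_repetitions Integer set of training repetition indices.
#' @param test_repetitions Integer set of test repetition indices.
#' @return An object of class `split_spec`.
#' @examples
#' split_spec()   # train 1,3:6,8:10 / test 2,7
#' @export
split_spec <- function(train_repetitions = c(1L, 3:6, 8:10),
                       test_repetitions = c(2L, 7L)) {
  train_repetitions <- as.integer(train_repetitions)
  test_repetitions <- as.integer(test_repetitions)
  if (length(train_repetitions) == 0L || length(test_repetitions) == 0L) {
    abort("Both repetition sets must be non-empty.",
          class = "semg_config_error")
  }
  if (length(intersect(train_repetitions, test_repetitions)) > 0L) {
    abort("Train and test repetition sets must be disjoint.",
          class = "semg_config_error")
  }
  structure(list(train_repetitions = train_repetitions,
                 test_repetitions = test_repetitions),
            class = "split_spec")
}

#' Discover pre-segmented Ninapro-style recordings in a directory
#'
#' Scans for `.mat` files named `SSS_GGG_RRR.mat` (subject, stimulus and
#' repetition, each zero-padded to three digits, e.g. `001_002_003.mat` for
#' the third repetition of the second stimulus of the first subject).
#' Files that do not match the pattern are returned with `malformed = TRUE`
#' and reported, not silently skipped.
#'
#' @param root_path Directory to scan.
#' @return A tibble with columns `path`, `file`, `subject`, `stimulus`,
#'   `repetition`, `malformed`.
#' @export
discover_recordings <- function(root_path) {
  if (!dir.exists(root_path)) {
    abort(sprintf("Directory not found: %s", root_path),
          class = "semg_io_error")
  }
  files <- sort(list.files(root_path, pattern = "\\.mat$", ignore.case = TRUE))
  if (length(files) == 0L) {
    warn(sprintf("No .mat files found in %s.", root_path))
  }
  pat <- "^([0-9]{3})_([0-9]{3})_([0-9]{3})\\.mat$"
  ok <- grepl(pat, files)
  if (any(!ok)) {
    warn(sprintf("Malformed recording filenames (expected SSS_GGG_RRR.mat): %s",
                 paste(files[!ok], collapse = ", ")))
  }
  parse_field <- function(i) {
    out <- rep(NA_integer_, length(files))
    out[ok] <- as.integer(sub(pat, paste0("\\", i), files[ok]))
    out
  }
  tibble::tibble(
    path = file.path(root_path, files),
    file = files,
    subject = parse_field(1),
    stimulus = parse_field(2),
    repetition = parse_field(3),
    malformed = !ok
  )
}

# normalise the various ways recordings can be handed in
as_recording_list <- function(recordings, fs = 100) {
  if (is_recording(recordings)) return(list(recordings))
  if (is.data.frame(recordings)) {
    recs <- recordings[!recordings$malformed, , drop = FALSE]
    return(purrr::pmap(
      recs[, c("path", "subject", "stimulus", "repetition")],
      function(path, subject, stimulus, repetition) {
        read_ninapro_mat(path, subject = subject, stimulus = stimulus,
                         repetition = repetition, fs = fs)
      }))
  }
  if (is.list(recordings) && all(vapply(recordings, is_recording, TRUE))) {
    return(recordings)
  }
  abort(paste("`recordings` must be an semg_recording, a list of them, or a",
              "discover_recordings() table."))
}

new_semg_dataset <- function(samples, class_count, classes, dims, Q,
                             gadf_formula) {
  flat <- function(stream) {
    if (nrow(samples) == 0L) {
      return(matrix(numeric(0), 0L, prod(dims[[stream]])))
    }
    do.call(rbind, lapply(samples[[stream]], as.vector))
  }
  images <- list(sigimg = flat("sigimg"), gadf = flat("gadf"),
                 mtf = flat("mtf"))
  manifest <- samples[, c("label", "class", "subject", "repetition",
                          "start_index")]
  structure(
    list(images = images, dims = dims,
         labels = as.integer(samples$class),
         class_count = as.integer(class_count),
         classes = classes, manifest = manifest,
         Q = as.integer(Q), gadf_formula = gadf_formula),
    class = "semg_dataset"
  )
}

#' @export
print.semg_dataset <- function(x, ...) {
  cat(sprintf("<semg_dataset> %d samples, %d classes\n",
              length(x$labels), x$class_count))
  for (nm in names(x$images)) {
    cat(sprintf("  %-6s %d x %d images\n", nm, x$dims[[nm]][1],
                x$dims[[nm]][2]))
  }
  invisible(x)
}

#' Number of samples in a dataset
#' @param x An `semg_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) length(x$labels)

subset_dataset <- function(ds, idx) {
  ds$images <- lapply(ds$images, function(m) m[idx, , drop = FALSE])
  ds$labels <- ds$labels[idx]
  ds$manifest <- ds$manifest[idx, , drop = FALSE]
  ds
}

#' Build train and test image datasets from recordings
#'
#' Windows every recording, encodes each window as the (Sigimg, GADF, MTF)
#' image triple, and partitions the windows by repetition according to the
#' split specification: every window of a training repetition lands in the
#' training set and likewise for test, so no movement execution leaks across
#' the partition.  Stimulus labels are remapped to contiguous 0-based class
#' indices; the mapping is recorded in each dataset (`classes`).
#'
#' Sample order is canonical (sorted by subject, stimulus, repetition,
#' window offset), so shuffling the discovery order of the recordings yields
#' identical datasets.
#'
#' @param recordings A list of [semg_recording()] objects or a
#'   [discover_recordings()] table.
#' @param window_spec A [window_spec()].
#' @param split A [split_spec()].
#' @param Q Number of MTF quantile bins.
#' @param gadf_formula See [gadf_matrix()].
#' @param fs Sampling rate used when loading recordings from files.
#' @return A list with `train` and `test`, both `semg_dataset` objects.
#' @export
build_dataset <- function(recordings, window_spec = semgimage::window_spec(),
                          split = split_spec(), Q = 8L,
                          gadf_formula = c("cos_diff", "sin_diff"),
                          fs = 100) {
  gadf_formula <- match.arg(gadf_formula)
  recs <- as_recording_list(recordings, fs = fs)
  if (length(recs) == 0L) abort("No recordings to build a dataset from.")
  reps <- unique(vapply(recs, function(r) r$repetition, integer(1)))
  known <- c(split$train_repetitions, split$test_repetitions)
  if (any(!reps %in% known)) {
    abort(sprintf("Repetition(s) %s belong to neither split.",
                  paste(setdiff(reps, known), collapse = ", ")),
          class = "semg_config_error")
  }
  if (any(!known %in% reps)) {
    warn(sprintf("Split repetition(s) %s not present in the data.",
                 paste(setdiff(known, reps), collapse = ", ")))
  }
  windows <- dplyr::bind_rows(lapply(recs, sliding_windows, spec = window_spec))
  if (nrow(windows) == 0L) abort("All recordings are shorter than the window.")
  windows <- dplyr::arrange(windows, .data$subject, .data$label,
                            .data$repetition, .data$start_index)
  classes <- sort(unique(windows$label))
  windows$class <- match(windows$label, classes) - 1L
  windows <- encode_windows(windows, Q = Q, gadf_formula = gadf_formula)
  dims <- list(sigimg = dim(windows$sigimg[[1]]),
               gadf = dim(windows$gadf[[1]]),
               mtf = dim(windows$mtf[[1]]))
  in_train <- windows$repetition %in% split$train_repetitions
  mk <- function(rows) {
    new_semg_dataset(windows[rows, , drop = FALSE], length(classes), classes,
                     dims, Q, gadf_formula)
  }
  list(train = mk(which(in_train)), test = mk(which(!in_train)))
}
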