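#' Pipeline configuration
#'
#' Bundles every stage parameter of the simulate/encode/split/train/evaluate
#' pipeline into one validated object.  All randomness flows from
#' `training$seed` and (for synthetic data) `synth$seed`.
#'
#' @param synth A [synth_config()] to generate data, or `NULL` to load
#'   pre-segmented MAT files from `data_dir`.
#' @param data_dir Directory of `SSS_GGG_RRR.mat` files (used when `synth`
#'   is `NULL`).
#' @param window A [window_spec()].
#' @param Q MTF quantile bins.
#' @param gadf_formula See [gadf_matrix()].
#' @param split A [split_spec()].
#' @param arch `"mscnn"`, `"dscnn"` or `"sscnn"`.
#' @param streams Streams fed to the model (subset of
#'   `c("sigimg", "gadf", "mtf")` consistent with `arch`).
#' @param scale Width multiplier for the network (see [mscnn_spec()]).
#' @param training A [train_config()].
#' @param out_dir Where `run_pipeline()` writes its artifacts; `NULL`
#'   disables writing.
#' @param fs Sampling rate assumed when loading MAT files.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = NULL, data_dir = NULL,
                            window = window_spec(), Q = 8L,
                            gadf_formula = "cos_diff",
                            split = split_spec(), arch = "mscnn",
                            streams = c("sigimg", "gadf", "mtf"),
                            scale = 1, training = train_config(),
                            out_dir = NULL, fs = 100) {
  if (is.null(synth) && is.null(data_dir)) {
    abort("Provide either `synth` or `data_dir`.",
          class = "semg_config_error")
  }
  if (!arch %in% c("mscnn", "dscnn", "sscnn")) {
    abort(sprintf("Unknown architecture '%s'.", arch),
          class = "semg_config_error")
  }
  need <- c(mscnn = 3L, dscnn = 2L, sscnn = 1L)[[arch]]
  if (length(streams) != need) {
    abort(sprintf("`%s` needs exactly %d stream(s).", arch, need),
          class = "semg_config_error")
  }
  structure(list(synth = synth, data_dir = data_dir, window = window,
                 Q = as.integer(Q), gadf_formula = gadf_formula,
                 split = split, arch = arch, streams = streams,
                 scale = scale, training = training, out_dir = out_dir,
                 fs = fs),
            class = "pipeline_config")
}

model_spec_for <- function(config, dims, class_count) {
  switch(config$arch,
    mscnn = mscnn_spec(class_count, dims, scale = config$scale),
    dscnn = dscnn_spec(config$streams, class_count, dims,
                       scale = config$scale),
    sscnn = sscnn_spec(config$streams, class_count, dims,
                       scale = config$scale))
}

#' Run the full gesture-recognition pipeline
#'
#' Executes the stages in order -- generate or load recordings, segment and
#' encode windows, split by repetition, train the configured network, and
#' evaluate on the held-out repetitions -- and (optionally) writes the
#' evaluation report (JSON), the training history and confusion matrix
#' (CSV), the sample manifest (CSV) and the resolved configuration (JSON)
#' to `out_dir`.  Re-running with an identical configuration reproduces the
#' report exactly.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return A list with the `fit` (`semg_cnn_fit`), the `report`
#'   (`semg_eval`), the `datasets` pair, and `paths` of written artifacts.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stage <- function(name, expr) {
    if (verbose) message(sprintf("[%s]", name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), class = "semg_pipeline_error")
    })
  }
  recs <- stage("data", {
    if (!is.null(config$synth)) {
      generate_semg(config$synth)
    } else {
      discover_recordings(config$data_dir)
    }
  })
  sets <- stage("dataset", {
    build_dataset(recs, window_spec = config$window, split = config$split,
                  Q = config$Q, gadf_formula = config$gadf_formula,
                  fs = config$fs)
  })
  spec <- model_spec_for(config, sets$train$dims, sets$train$class_count)
  fit <- stage("train", train(spec, sets$train, config$training,
                              verbose = verbose))
  report <- stage("evaluate", evaluate(fit, sets$test))
  paths <- list()
  if (!is.null(config$out_dir)) {
    paths <- stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      p <- list(
        report = file.path(config$out_dir, "report.json"),
        history = file.path(config$out_dir, "history.csv"),
        confusion = file.path(config$out_dir, "confusion.csv"),
        manifest = file.path(config$out_dir, "manifest.csv"),
        config = file.path(config$out_dir, "config.json"))
      jsonlite::write_json(
        list(mean_accuracy = report$mean_accuracy,
             accuracy = report$accuracy, precision = report$precision,
             recall = report$recall,
             per_subject = report$per_subject),
        p$report, auto_unbox = TRUE, digits = NA)
      readr::write_csv(fit$history, p$history)
      utils::write.csv(report$confusion, p$confusion)
      manifest <- dplyr::bind_rows(
        dplyr::mutate(sets$train$manifest, split = "train"),
        dplyr::mutate(sets$test$manifest, split = "test"))
      readr::write_csv(manifest, p$manifest)
      jsonlite::write_json(serialize_config(config), p$config,
                           auto_unbox = TRUE, digits = NA)
      p
    })
  }
  list(fit = fit, report = report, datasets = sets, paths = paths)
}

serialize_config <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  strip(config)
}
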