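# shared fixtures, built once per test run

`%||%` <- function(a, b) if (is.null(a)) b else a

make_recording <- function(n = 100, channels = 3, fs = 100, subject = 1L,
                           stimulus = 1L, repetition = 1L, seed = 1L) {
  set.seed(seed)
  semg_recording(matrix(abs(rnorm(n * channels)), n, channels), fs = fs,
                 subject = subject, stimulus = stimulus,
                 repetition = repetition)
}

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small 4-channel, 2-subject, 2-gesture dataset used by the model and
# training tests (images: sigimg 20x16, gadf/mtf 20x80)
tiny_sets <- function() {
  fixture("tiny_sets", function() {
    recs <- generate_semg(synth_config(subjects = 2, gestures = 2,
                                       repetitions = 10, channels = 4,
                                       duration_s = 1, seed = 11))
    build_dataset(recs)
  })
}

tiny_spec <- function(class_count = 2L) {
  sets <- tiny_sets()
  mscnn_spec(class_count, dims = sets$train$dims, scale = 0.125)
}

quick_config <- function(epochs = 2L, seed = 1L) {
  train_config(batch_size = 50L, epochs = epochs, lr_initial = 1e-3,
               lr_drop_epochs = integer(0), seed = seed)
}

# fixed-prediction stand-in used to test the metric computations in
# isolation from any trained network
stub_model <- function(pred) {
  structure(list(pred = pred), class = "stub_model")
}

registerS3method("predict", "stub_model", function(object, newdata, ...) {
  p <- object$pred
  if (length(p) == 1L) rep(p, n_samples(newdata)) else p
}, envir = asNamespace("stats"))
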