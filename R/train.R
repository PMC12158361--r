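#' Training configuration
#'
#' Defaults follow the reference schedule: Adam with cross-entropy loss,
#' batch size 100, 30 epochs, an initial learning rate of 0.1 divided by 10
#' at the start of epochs 16 and 24, and dropout 0.5 before each fully
#' connected layer.  For desk-scale experiments a flat small rate
#' (`lr_initial = 1e-3`, no drops) is usually the better choice with Adam;
#' see the package vignette.
#'
#' @param batch_size Mini-batch size.
#' @param epochs Number of training epochs.
#' @param lr_initial Initial learning rate.
#' @param lr_drop_epochs Epochs at which the rate is divided by
#'   `lr_drop_factor`.
#' @param lr_drop_factor Division factor at each drop.
#' @param dropout Dropout rate before each fully connected layer.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 100L, epochs = 30L, lr_initial = 0.1,
                         lr_drop_epochs = c(16L, 24L), lr_drop_factor = 10,
                         dropout = 0.5, seed = 1L) {
  if (batch_size < 1L || epochs < 1L || lr_initial <= 0 ||
      lr_drop_factor <= 0 || dropout < 0 || dropout >= 1) {
    abort("Invalid training configuration.", class = "semg_config_error")
  }
  if (length(lr_drop_epochs) > 0 &&
      any(lr_drop_epochs < 1L | lr_drop_epochs > epochs)) {
    abort("`lr_drop_epochs` must lie within 1..epochs.",
          class = "semg_config_error")
  }
  structure(list(optimizer = "adam", loss = "cross_entropy",
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_initial = lr_initial,
                 lr_drop_epochs = as.integer(lr_drop_epochs),
                 lr_drop_factor = lr_drop_factor, dropout = dropout,
                 seed = as.integer(seed)),
            class = "train_config")
}

lr_at_epoch <- function(config, epoch) {
  config$lr_initial / config$lr_drop_factor^sum(epoch >= config$lr_drop_epochs)
}

#' Train a CNN on an image dataset
#'
#' Runs mini-batch Adam with cross-entropy loss for exactly
#' `config$epochs` epochs under the piecewise-constant learning-rate
#' schedule of [train_config()].  Training is fully reproducible: the seed
#' drives weight initialisation, shuffling and dropout, so two runs with the
#' same seed and data give identical results.
#'
#' @param model_spec A `model_spec` from [mscnn_spec()], [sscnn_spec()] or
#'   [dscnn_spec()].
#' @param train_dataset An `semg_dataset` (from [build_dataset()]).
#' @param config A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return An object of class `semg_cnn_fit` holding the trained
#'   parameters, the spec and config, and a per-epoch `history` tibble
#'   (`epoch`, `lr`, `loss`, `accuracy`).
#' @export
train <- function(model_spec, train_dataset, config = train_config(),
                  verbose = FALSE) {
  if (n_samples(train_dataset) == 0L) {
    abort("Training dataset is empty.", class = "semg_config_error")
  }
  for (s in model_spec$streams) {
    have <- ncol(train_dataset$images[[s]])
    want <- prod(model_spec$branches[[s]]$input_shape)
    if (is.null(have) || have != want) {
      abort(sprintf(
        "Stream '%s': dataset images have %s pixels but the model expects %d.",
        s, have %||% "no", want), class = "semg_config_error")
    }
  }
  if (max(train_dataset$labels) + 1L > model_spec$class_count) {
    abort("Dataset has more classes than the model output layer.",
          class = "semg_config_error")
  }
  set.seed(config$seed)
  net <- init_network(model_spec)
  state <- list(t = 0L, m = zeros_like_tree(net$par),
                v = zeros_like_tree(net$par))
  n <- n_samples(train_dataset)
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch)
    ord <- sample.int(n)
    losses <- c(); accs <- c()
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      step <- network_train_step(
        net, state,
        dataset_inputs(train_dataset, model_spec$streams, idx),
        train_dataset$labels[idx], lr, config$dropout)
      net <- step$net
      state <- step$state
      losses <- c(losses, step$loss)
      accs <- c(accs, step$acc)
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, lr = lr, loss = mean(losses), accuracy = mean(accs))
    if (verbose) {
      message(sprintf("epoch %2d  lr %.4g  loss %.4f  acc %.3f",
                      epoch, lr, mean(losses), mean(accs)))
    }
  }
  structure(
    list(spec = model_spec, config = config, net = net,
         history = dplyr::bind_rows(history),
         classes = train_dataset$classes),
    class = "semg_cnn_fit"
  )
}

#' @export
print.semg_cnn_fit <- function(x, ...) {
  cat(sprintf("<semg_cnn_fit> %s, %d classes, %d epochs\n", x$spec$name,
              x$spec$class_count, nrow(x$history)))
  h <- tail(x$history, 1)
  cat(sprintf("  final training loss %.4f, accuracy %.3f\n",
              h$loss, h$accuracy))
  invisible(x)
}

#' Predict gesture classes for a dataset
#'
#' @param object A fitted `semg_cnn_fit`.
#' @param newdata An `semg_dataset` with the streams the model expects.
#' @param type `"class"` for 0-based class indices, `"label"` for the
#'   original stimulus labels, `"prob"` for the softmax matrix.
#' @param ... Unused.
#' @return Integer vector or probability matrix.
#' @export
predict.semg_cnn_fit <- function(object, newdata,
                                 type = c("class", "label", "prob"), ...) {
  type <- match.arg(type)
  probs <- network_predict(object$net, newdata)
  if (type == "prob") return(probs)
  cls <- max.col(probs) - 1L
  if (type == "class") cls else object$classes[cls + 1L]
}

#' @rdname tidy_semg
#' @export
tidy.semg_cnn_fit <- function(x, ...) x$history

#' Tidiers for fitted networks and evaluation reports
#'
#' `tidy()` on a fit returns the per-epoch training history; `glance()`
#' returns a one-row summary.  `tidy()` on an evaluation report returns the
#' per-class precision/recall table; `glance()` the headline metrics.
#'
#' @param x A `semg_cnn_fit` or `semg_eval` object.
#' @param ... Unused.
#' @name tidy_semg
#' @return A tibble.
#' @export
glance.semg_cnn_fit <- function(x, ...) {
  h <- tail(x$history, 1)
  tibble::tibble(model = x$spec$name, epochs = nrow(x$history),
                 final_loss = h$loss, final_accuracy = h$accuracy,
                 macs = count_macs(x$spec))
}

#' Plot the training history of a fit
#'
#' @param object A `semg_cnn_fit`.
#' @param ... Unused.
#' @return A ggplot of loss and training accuracy by epoch.
#' @export
autoplot.semg_cnn_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("loss", "accuracy"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

# ---- evaluation -------------------------------------------------------------

#' Evaluate a fitted model on a test dataset
#'
#' Computes per-subject accuracy (correct windows over total windows for
#' that subject), their mean across subjects, per-class precision and
#' recall from true/false positives and negatives with macro (default) or
#' micro averaging, and the confusion matrix (rows = true class, columns =
#' predicted class).
#'
#' @param model A fitted `semg_cnn_fit` (or any object whose
#'   [predict()] method returns 0-based class indices for an
#'   `semg_dataset`).
#' @param test_dataset An `semg_dataset`.
#' @param average `"macro"` or `"micro"` precision/recall averaging.
#' @return An object of class `semg_eval`: a list with `accuracy`,
#'   `per_subject` (tibble), `mean_accuracy`, `precision`, `recall`,
#'   `per_class` (tibble) and `confusion` (matrix).
#' @export
evaluate <- function(model, test_dataset, average = c("macro", "micro")) {
  average <- match.arg(average)
  if (n_samples(test_dataset) == 0L) {
    abort("Test dataset is empty.", class = "semg_config_error")
  }
  pred <- predict(model, test_dataset, type = "class")
  truth <- test_dataset$labels
  k <- test_dataset$class_count
  confusion <- table(factor(truth, levels = 0:(k - 1)),
                     factor(pred, levels = 0:(k - 1)))
  confusion <- matrix(as.integer(confusion), k, k,
                      dimnames = list(true = test_dataset$classes,
                                      predicted = test_dataset$classes))
  subj <- test_dataset$manifest$subject
  per_subject <- tibble::tibble(subject = sort(unique(subj))) |>
    dplyr::mutate(
      n = vapply(.data$subject, function(s) sum(subj == s), integer(1)),
      correct = vapply(.data$subject,
                       function(s) sum(pred[subj == s] == truth[subj == s]),
                       integer(1)),
      accuracy = .data$correct / .data$n)
  tp <- unname(diag(confusion))
  fp <- unname(colSums(confusion)) - tp
  fn <- unname(rowSums(confusion)) - tp
  per_class <- tibble::tibble(
    class = test_dataset$classes,
    n = rowSums(confusion),
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    recall = ifelse(tp + fn > 0, tp / (tp + fn), NA_real_))
  if (average == "macro") {
    precision <- mean(per_class$precision, na.rm = TRUE)
    recall <- mean(per_class$recall, na.rm = TRUE)
  } else {
    precision <- sum(tp) / sum(tp + fp)
    recall <- sum(tp) / sum(tp + fn)
  }
  structure(
    list(accuracy = mean(pred == truth),
         per_subject = per_subject,
         mean_accuracy = mean(per_subject$accuracy),
         precision = precision, recall = recall, average = average,
         per_class = per_class, confusion = confusion),
    class = "semg_eval"
  )
}

#' @export
print.semg_eval <- function(x, ...) {
  cat("<semg_eval>\n")
  cat(sprintf("  mean per-subject accuracy: %.1f%% (%d subjects)\n",
              100 * x$mean_accuracy, nrow(x$per_subject)))
  cat(sprintf("  overall accuracy: %.1f%%\n", 100 * x$accuracy))
  cat(sprintf("  precision (%s): %.1f%%   recall (%s): %.1f%%\n",
              x$average, 100 * x$precision, x$average, 100 * x$recall))
  invisible(x)
}

#' @rdname tidy_semg
#' @export
tidy.semg_eval <- function(x, ...) x$per_class

#' @rdname tidy_semg
#' @export
glance.semg_eval <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean_accuracy, accuracy = x$accuracy,
                 precision = x$precision, recall = x$recall,
                 n_subjects = nrow(x$per_subject),
                 n_samples = sum(x$confusion))
}

#' Plot an evaluation confusion matrix
#'
#' @param object An `semg_eval`.
#' @param normalise Normalise rows to proportions.
#' @param ... Unused.
#' @return A ggplot heat map, rows = true class, columns = predicted.
#' @export
autoplot.semg_eval <- function(object, normalise = TRUE, ...) {
  m <- object$confusion
  if (normalise) {
    rs <- rowSums(m)
    m <- sweep(m, 1, pmax(rs, 1), "/")
  }
  df <- tibble::tibble(
    true = factor(rep(rownames(object$confusion), times = ncol(m))),
    predicted = factor(rep(colnames(object$confusion), each = nrow(m))),
    value = as.vector(t(m)))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = if (normalise) "rate" else "count") +
    ggplot2::labs(x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

# ---- cross-validation -------------------------------------------------------

#' Repeated stratified k-fold cross-validation
#'
#' Partitions the dataset into `folds` class-stratified folds, trains on
#' all-but-one and tests on the held-out fold, and repeats the whole
#' procedure `repeats` times with reshuffled folds (fold seeds are derived
#' as `config$seed + repeat`).  Classes with fewer samples than folds
#' trigger a warning and a non-stratified split.
#'
#' @param dataset An `semg_dataset`.
#' @param model_spec A `model_spec`.
#' @param config A [train_config()].
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeats (default 10).
#' @param fit_fun Optional `function(train_dataset, model_spec, config)`
#'   returning an object with a class-index `predict()` method; defaults to
#'   [train()].
#' @return A list with `mean_accuracy`, `sd_accuracy`, and a `runs` tibble
#'   (`repeat`, `fold`, `accuracy`).
#' @export
cross_validate <- function(dataset, model_spec, config = train_config(),
                           folds = 5L, repeats = 10L, fit_fun = NULL) {
  n <- n_samples(dataset)
  if (n < folds) abort("Dataset smaller than the number of folds.",
                       class = "semg_config_error")
  if (is.null(fit_fun)) {
    fit_fun <- function(tr, spec, cfg) train(spec, tr, cfg)
  }
  class_sizes <- table(dataset$labels)
  stratified <- all(class_sizes >= folds)
  if (!stratified) {
    warn("Some classes have fewer samples than folds; using a non-stratified split.")
  }
  runs <- list()
  for (r in seq_len(repeats)) {
    set.seed(config$seed + r)
    fold_of <- integer(n)
    if (stratified) {
      for (cl in unique(dataset$labels)) {
        idx <- sample(which(dataset$labels == cl))
        fold_of[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      fold_of <- sample(rep_len(seq_len(folds), n))
    }
    for (f in seq_len(folds)) {
      fit <- fit_fun(subset_dataset(dataset, which(fold_of != f)),
                     model_spec, config)
      te <- subset_dataset(dataset, which(fold_of == f))
      acc <- mean(predict(fit, te, type = "class") == te$labels)
      runs[[length(runs) + 1L]] <- tibble::tibble(
        rep = r, fold = f, accuracy = acc)
    }
  }
  runs <- dplyr::bind_rows(runs)
  list(mean_accuracy = mean(runs$accuracy),
       sd_accuracy = sd(runs$accuracy), runs = runs)
}
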