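# Declarative CNN architecture specs.  A branch is a stack of stride-1
# padded convolutions and 2x2/stride-2 max-pool layers over one image
# stream; a model is 1-3 branches whose flattened features are concatenated
# into a shared fully connected stack ending in a softmax over the classes.

conv_layer <- function(filters, kernel, pad, stride = 1L) {
  list(type = "conv", filters = as.integer(filters),
       kernel = as.integer(kernel), pad = as.integer(pad),
       stride = as.integer(stride))
}

pool_layer <- function(size = 2L, stride = 2L) {
  list(type = "maxpool", size = as.integer(size), stride = as.integer(stride))
}

new_branch_spec <- function(input_shape, layers) {
  br <- structure(list(input_shape = as.integer(input_shape), layers = layers),
                  class = "branch_spec")
  br$flatten_size <- tail(trace_branch(br)$flat, 1L)
  br
}

# the Table-1 style two-conv/two-pool branch for one stream
stream_branch <- function(stream, dims, scale = 1) {
  f1 <- max(1L, as.integer(round(16 * scale)))
  f2 <- max(1L, as.integer(round(32 * scale)))
  k2 <- if (stream == "sigimg") c(3L, 3L) else c(5L, 5L)
  p2 <- if (stream == "sigimg") 1L else 2L
  new_branch_spec(
    c(dims, 1L),
    list(conv_layer(f1, c(3L, 3L), pad = 1L), pool_layer(),
         conv_layer(f2, k2, pad = p2), pool_layer())
  )
}

#' Trace the feature-map shape through a branch
#'
#' @param branch A `branch_spec`.
#' @return A tibble with one row per layer: `layer`, `type`, `out_h`,
#'   `out_w`, `out_c`, and the running `flat` size (`out_h * out_w * out_c`).
#' @export
trace_branch <- function(branch) {
  h <- branch$input_shape[1]; w <- branch$input_shape[2]
  c <- branch$input_shape[3]
  rows <- purrr::imap(branch$layers, function(ly, i) {
    if (ly$type == "conv") {
      h <<- (h + 2L * ly$pad - ly$kernel[1]) %/% ly$stride + 1L
      w <<- (w + 2L * ly$pad - ly$kernel[2]) %/% ly$stride + 1L
      c <<- ly$filters
    } else {
      h <<- h %/% ly$stride
      w <<- w %/% ly$stride
    }
    tibble::tibble(layer = i, type = ly$type, out_h = h, out_w = w,
                   out_c = c, flat = h * w * c)
  })
  dplyr::bind_rows(rows)
}

db1_image_dims <- function(tw = 20L, channels = 10L) {
  list(sigimg = c(tw, channels^2), gadf = c(tw, channels * tw),
       mtf = c(tw, channels * tw))
}

new_model_spec <- function(name, branches, fusion_fc, class_count,
                           dropout_rate = 0.5, batchnorm = TRUE) {
  structure(
    list(name = name, streams = names(branches), branches = branches,
         fusion_fc = as.integer(c(fusion_fc, class_count)),
         class_count = as.integer(class_count),
         dropout_rate = dropout_rate, batchnorm = batchnorm),
    class = "model_spec"
  )
}

#' Three-stream CNN specification
#'
#' The full three-branch network: a Sigimg branch (3x3 kernels throughout)
#' and GADF/MTF branches (3x3 then 5x5 kernels), each two conv + two pool
#' layers with batch normalisation and ReLU, flattened, concatenated, and
#' fused through fully connected layers of 4096 and 2048 units (ReLU,
#' dropout 0.5 before each) into a softmax over the classes.  For the
#' standard 20-sample, 10-channel configuration the branch flatten sizes are
#' 4000, 8000 and 8000 (concatenated 20000).
#'
#' @param class_count Number of gesture classes (>= 2).
#' @param dims Named list of image heights/widths per stream; defaults to
#'   the 20 x 100 / 20 x 200 / 20 x 200 shapes of a 20-sample, 10-channel
#'   window.
#' @param scale Width multiplier applied to filter counts and fusion layer
#'   sizes; `scale = 0.5` gives the half-width network used for desk-scale
#'   experiments.
#' @return A `model_spec`.
#' @examples
#' spec <- mscnn_spec(52)
#' vapply(spec$branches, function(b) b$flatten_size, integer(1))
#' @export
mscnn_spec <- function(class_count = 52L, dims = db1_image_dims(),
                       scale = 1) {
  if (class_count < 2L) abort("`class_count` must be >= 2.",
                              class = "semg_config_error")
  streams <- c("sigimg", "gadf", "mtf")
  branches <- setNames(
    lapply(streams, function(s) stream_branch(s, dims[[s]], scale)), streams)
  fc <- pmax(1L, as.integer(round(c(4096L, 2048L) * scale)))
  new_model_spec("mscnn", branches, fc, class_count)
}

#' Single-stream CNN specification
#'
#' One branch identical to the corresponding three-stream branch, with a
#' fully connected stack of 1024/256 units for the Sigimg stream and
#' 2048/512 for the GADF or MTF streams, ending in the class softmax.
#'
#' @param stream One of `"sigimg"`, `"gadf"`, `"mtf"`.
#' @inheritParams mscnn_spec
#' @return A `model_spec`.
#' @export
sscnn_spec <- function(stream, class_count = 52L, dims = db1_image_dims(),
                       scale = 1) {
  if (!stream %in% c("sigimg", "gadf", "mtf")) {
    abort(sprintf("Unknown stream '%s'.", stream),
          class = "semg_config_error")
  }
  branches <- setNames(list(stream_branch(stream, dims[[stream]], scale)),
                       stream)
  fc <- if (stream == "sigimg") c(1024L, 256L) else c(2048L, 512L)
  fc <- pmax(1L, as.integer(round(fc * scale)))
  new_model_spec(paste0(stream, "-sscnn"), branches, fc, class_count)
}

#' Dual-stream CNN specification
#'
#' Two branches (either Sigimg + GADF or GADF + MTF) fused through fully
#' connected layers of 4096 and 1024 units into the class softmax.
#'
#' @param streams Character pair: `c("sigimg", "gadf")` or
#'   `c("gadf", "mtf")`.
#' @inheritParams mscnn_spec
#' @return A `model_spec`.
#' @export
dscnn_spec <- function(streams, class_count = 52L, dims = db1_image_dims(),
                       scale = 1) {
  ok <- identical(streams, c("sigimg", "gadf")) ||
    identical(streams, c("gadf", "mtf"))
  if (!ok) {
    abort("`streams` must be c('sigimg','gadf') or c('gadf','mtf').",
          class = "semg_config_error")
  }
  branches <- setNames(
    lapply(streams, function(s) stream_branch(s, dims[[s]], scale)), streams)
  fc <- pmax(1L, as.integer(round(c(4096L, 1024L) * scale)))
  new_model_spec(paste(paste(streams, collapse = "-"), "dscnn", sep = "-"),
                 branches, fc, class_count)
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s: %d stream(s), %d classes\n", x$name,
              length(x$branches), x$class_count))
  for (s in names(x$branches)) {
    b <- x$branches[[s]]
    cat(sprintf("  %-6s in %dx%d -> flatten %d\n", s, b$input_shape[1],
                b$input_shape[2], b$flatten_size))
  }
  cat(sprintf("  fusion FC: %s (dropout %.2f%s)\n",
              paste(x$fusion_fc, collapse = " -> "), x$dropout_rate,
              if (x$batchnorm) ", batchnorm" else ""))
  cat(sprintf("  MACs: %.1f M\n", count_macs(x) / 1e6))
  invisible(x)
}

#' Multiply-accumulate count of a model
#'
#' Counts one MAC per multiply in the convolutions
#' (`outH * outW * outC * kernelH * kernelW * inC` per conv layer) and the
#' fully connected layers (`in * out`); pooling, batch normalisation, biases
#' and activations contribute nothing.  Divide by `1e6` for the
#' conventional report in millions.
#'
#' @param spec A `model_spec`.
#' @return Total MAC count (a double).
#' @export
count_macs <- function(spec) {
  total <- 0
  for (b in spec$branches) {
    h <- b$input_shape[1]; w <- b$input_shape[2]; c <- b$input_shape[3]
    for (ly in b$layers) {
      if (ly$type == "conv") {
        oh <- (h + 2 * ly$pad - ly$kernel[1]) %/% ly$stride + 1
        ow <- (w + 2 * ly$pad - ly$kernel[2]) %/% ly$stride + 1
        total <- total + oh * ow * ly$filters * ly$kernel[1] * ly$kernel[2] * c
        h <- oh; w <- ow; c <- ly$filters
      } else {
        h <- h %/% ly$stride; w <- w %/% ly$stride
      }
    }
  }
  fan_in <- sum(vapply(spec$branches, function(b) b$flatten_size, integer(1)))
  for (out in spec$fusion_fc) {
    total <- total + fan_in * out
    fan_in <- out
  }
  total
}
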