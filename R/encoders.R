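#' Rescale a series to the symmetric unit interval
#'
#' Min-max rescaling to the symmetric unit interval,
#' \eqn{\tilde x_i = (x_i - \max X + x_i - \min X) / (\max X - \min X)},
#' the standard first step of Gramian angular field encoding.  A constant
#' series (zero range) maps to all zeros, the interval midpoint.
#'
#' @param series Numeric vector of length >= 1.
#' @return Numeric vector of the same length with values in `[-1, 1]`.
#' @examples
#' rescale_unit(c(0, 5, 10))   # -1 0 1
#' @export
rescale_unit <- function(series) {
  if (length(series) < 1L) abort("`series` must be non-empty.")
  if (anyNA(series)) abort("`series` must not contain missing values.")
  rng <- range(series)
  if (rng[1] == rng[2]) return(rep(0, length(series)))
  (2 * series - rng[2] - rng[1]) / (rng[2] - rng[1])
}

#' Map a rescaled series to polar coordinates
#'
#' Angles are `acos` of the rescaled values (clipped to `[-1, 1]` at 1e-12
#' for floating-point safety), so a series in `[-1, 1]` maps to angles in
#' `[0, pi]`.  Radii are the 1-based timestamps divided by `N` (defaulting
#' to the series length); they are carried for completeness but the Gramian
#' matrix depends only on the angles.
#'
#' @param rescaled Numeric vector with values in `[-1, 1]`.
#' @param N Radius normalisation constant; defaults to `length(rescaled)`.
#' @return A list with numeric vectors `angles` (radians) and `radii`.
#' @export
to_polar <- function(rescaled, N = length(rescaled)) {
  if (any(abs(rescaled) > 1 + 1e-12)) {
    abort("`rescaled` values must lie in [-1, 1].")
  }
  list(angles = acos(pmin(1, pmax(-1, rescaled))),
       radii = seq_along(rescaled) / N)
}

#' Gramian angular difference field of a polar series
#'
#' Builds the n-by-n matrix `G[i, j] = cos(phi_i - phi_j)` (the default,
#' cosine-of-difference form) or the more common literature variant
#' `sin(phi_i - phi_j)` when `formula = "sin_diff"`.  The cosine form is
#' symmetric with a unit diagonal; the sine form is antisymmetric with a
#' zero diagonal.
#'
#' @param angles Numeric vector of angles in radians (from [to_polar()]),
#'   or a list with an `angles` element.
#' @param formula `"cos_diff"` (default) or `"sin_diff"`.
#' @return An n-by-n numeric matrix with entries in `[-1, 1]`.
#' @examples
#' g <- gadf_matrix(to_polar(rescale_unit(c(0, 5, 10)))$angles)
#' g   # [[1,0,-1],[0,1,0],[-1,0,1]]
#' @export
gadf_matrix <- function(angles, formula = c("cos_diff", "sin_diff")) {
  if (is.list(angles)) angles <- angles$angles
  formula <- match.arg(formula)
  d <- outer(angles, angles, "-")
  if (formula == "cos_diff") cos(d) else sin(d)
}

#' Quantile-bin a series for Markov transition field encoding
#'
#' Splits the value range into `Q` quantile bins of roughly equal sample
#' mass and assigns each sample its bin.  Intervals are half-open on the
#' right with the last interval closed, so every sample receives exactly one
#' bin in `0..Q-1`.  A constant series falls entirely into one bin.
#'
#' @param series Numeric vector of length >= 2.
#' @param Q Number of quantile bins (>= 2).
#' @return A list with `bins` (integer vector, 0-based) and `bin_edges`
#'   (Q+1 ascending values).
#' @examples
#' mtf_bins(c(1, 2, 1, 2), Q = 2)$bins   # 0 1 0 1
#' @export
mtf_bins <- function(series, Q = 8L) {
  if (Q < 2L) abort("`Q` must be >= 2.", class = "semg_config_error")
  if (length(series) < 2L) abort("`series` must have at least 2 samples.")
  edges <- quantile(series, probs = seq(0, 1, length.out = Q + 1),
                    names = FALSE, type = 7)
  # cut at the inner quantiles; ties in a non-decreasing cut vector simply
  # leave the earlier bins empty, so a constant series lands in one bin
  bins <- findInterval(series, edges[-c(1L, Q + 1L)])
  list(bins = as.integer(bins), bin_edges = edges)
}

#' Markov transition matrix of a binned series
#'
#' Estimates the Q-by-Q first-order Markov transition matrix along the
#' series: `W[a, b]` is the fraction of consecutive pairs that move from bin
#' `a` to bin `b`.  Bins with no outgoing transition get the uniform row
#' `1/Q`, so every row sums to one on all inputs.
#'
#' @param bins Integer vector of 0-based bin assignments (from
#'   [mtf_bins()]), or the list that function returns.
#' @param Q Number of bins.
#' @return A Q-by-Q row-stochastic numeric matrix.
#' @examples
#' mtf_transition(c(0L, 1L, 0L, 1L), Q = 2)   # [[0,1],[1,0]]
#' @export
mtf_transition <- function(bins, Q = 8L) {
  if (is.list(bins)) bins <- bins$bins
  n <- length(bins)
  if (n < 2L) abort("Need at least 2 samples to estimate transitions.")
  from <- bins[-n] + 1L
  to <- bins[-1L] + 1L
  W <- matrix(0, Q, Q)
  counts <- table(factor(from, levels = seq_len(Q)),
                  factor(to, levels = seq_len(Q)))
  W[] <- as.numeric(counts)
  rs <- rowSums(W)
  empty <- rs == 0
  W[!empty, ] <- W[!empty, , drop = FALSE] / rs[!empty]
  W[empty, ] <- 1 / Q
  W
}

#' Markov transition field of a series
#'
#' Spreads the transition matrix over time: `M[i, j] = W[bin(x_i), bin(x_j)]`
#' for all sample pairs in chronological order, giving an n-by-n image whose
#' entry couples the quantile states at times i and j.
#'
#' @param bins Integer vector of 0-based bin assignments (or [mtf_bins()]
#'   output).
#' @param W Row-stochastic transition matrix from [mtf_transition()].
#' @return An n-by-n numeric matrix with entries in `[0, 1]`.
#' @export
mtf_field <- function(bins, W) {
  if (is.list(bins)) bins <- bins$bins
  if (max(bins) + 1L > nrow(W)) {
    abort("Bin assignments exceed the transition matrix dimension.")
  }
  n <- length(bins)
  matrix(W[cbind(rep(bins + 1L, times = n), rep(bins + 1L, each = n))],
         nrow = n)
}

#' Channel-rearrangement (Sigimg) image of a multi-channel window
#'
#' Tiles the tw-by-C window horizontally into C blocks, block k being the
#' window with its columns cyclically rotated by k.  Block 0 is the original
#' window, the output is tw-by-C^2, every channel column appears exactly C
#' times, and every unordered channel pair ends up column-adjacent in at
#' least one block -- the property that lets small 2-D convolution kernels
#' see all cross-channel correlations.
#'
#' @param window A tw-by-C numeric matrix (one sliding window).
#' @return A tw-by-C^2 numeric matrix.
#' @examples
#' dim(sigimg(matrix(runif(200), 20, 10)))   # 20 100
#' @export
sigimg <- function(window) {
  window <- as.matrix(window)
  C <- ncol(window)
  if (C < 1L) abort("`window` must have at least one channel.")
  if (C == 1L) return(window)
  blocks <- lapply(seq_len(C) - 1L, function(k) {
    window[, ((seq_len(C) - 1L + k) %% C) + 1L, drop = FALSE]
  })
  do.call(cbind, blocks)
}

#' Horizontally stitch per-channel subimages
#'
#' Concatenates C equal-size n-by-n subimages into one n-by-(C n) image,
#' preserving channel order: column block c holds channel c's subimage
#' verbatim.
#'
#' @param subimages List of square numeric matrices of identical size.
#' @return An n-by-(C n) numeric matrix.
#' @export
stitch_subimages <- function(subimages) {
  if (length(subimages) < 1L) abort("`subimages` must be non-empty.")
  dims <- vapply(subimages, dim, integer(2))
  if (any(dims != dims[1, 1])) {
    abort("All subimages must be square matrices of equal size.")
  }
  do.call(cbind, subimages)
}

normalize01 <- function(m) {
  rng <- range(m)
  if (rng[1] == rng[2]) return(matrix(0, nrow(m), ncol(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

#' Encode one sliding window as the (Sigimg, GADF, MTF) image triple
#'
#' Applies the channel rearrangement to the whole window, and the
#' rescale-to-polar-to-GADF and quantile-bin-to-MTF transforms per channel
#' (each channel rescaled within the window, so windows are self-contained),
#' stitches the per-channel subimages horizontally, and min-max normalises
#' each of the three images to `[0, 1]`.
#'
#' @param window A tw-by-C numeric matrix.
#' @param Q Number of MTF quantile bins (default 8).
#' @param gadf_formula `"cos_diff"` (default) or `"sin_diff"`; see
#'   [gadf_matrix()].
#' @return A list of class `encoded_sample` with matrices `sigimg`
#'   (tw-by-C^2), `gadf` and `mtf` (both tw-by-(C tw)), all in `[0, 1]`.
#' @examples
#' enc <- encode_window(matrix(runif(200), 20, 10))
#' vapply(enc[c("sigimg", "gadf", "mtf")], dim, integer(2))
#' @export
encode_window <- function(window, Q = 8L,
                          gadf_formula = c("cos_diff", "sin_diff")) {
  window <- as.matrix(window)
  gadf_formula <- match.arg(gadf_formula)
  channels <- seq_len(ncol(window))
  gadf_sub <- lapply(channels, function(c) {
    gadf_matrix(to_polar(rescale_unit(window[, c]))$angles, gadf_formula)
  })
  mtf_sub <- lapply(channels, function(c) {
    b <- mtf_bins(window[, c], Q)
    mtf_field(b$bins, mtf_transition(b$bins, Q))
  })
  structure(
    list(sigimg = normalize01(sigimg(window)),
         gadf = normalize01(stitch_subimages(gadf_sub)),
         mtf = normalize01(stitch_subimages(mtf_sub)),
         Q = as.integer(Q), gadf_formula = gadf_formula),
    class = "encoded_sample"
  )
}

#' Encode every window of a windowed recording table
#'
#' Maps [encode_window()] over the `data` column of a [sliding_windows()]
#' table, adding `sigimg`, `gadf` and `mtf` list-columns next to the window
#' provenance.
#'
#' @param windows A tibble from [sliding_windows()] (or rows bound from
#'   several recordings).
#' @inheritParams encode_window
#' @return The input tibble with three image list-columns appended.
#' @export
encode_windows <- function(windows, Q = 8L,
                           gadf_formula = c("cos_diff", "sin_diff")) {
  gadf_formula <- match.arg(gadf_formula)
  enc <- lapply(windows$data, encode_window, Q = Q,
                gadf_formula = gadf_formula)
  windows$sigimg <- lapply(enc, `[[`, "sigimg")
  windows$gadf <- lapply(enc, `[[`, "gadf")
  windows$mtf <- lapply(enc, `[[`, "mtf")
  windows
}

#' @export
print.encoded_sample <- function(x, ...) {
  cat("<encoded_sample>\n")
  for (nm in c("sigimg", "gadf", "mtf")) {
    cat(sprintf("  %-6s %d x %d in [%.3f, %.3f]\n", nm,
                nrow(x[[nm]]), ncol(x[[nm]]), min(x[[nm]]), max(x[[nm]])))
  }
  cat(sprintf("  Q = %d, gadf_formula = %s\n", x$Q, x$gadf_formula))
  invisible(x)
}

#' Plot an encoded sample's three images
#'
#' @param object An `encoded_sample`.
#' @param ... Unused.
#' @return A ggplot object faceted by encoding.
#' @export
autoplot.encoded_sample <- function(object, ...) {
  df <- purrr::map_dfr(c("sigimg", "gadf", "mtf"), function(nm) {
    m <- object[[nm]]
    tibble::tibble(
      encoding = nm,
      row = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.vector(m)
    )
  })
  df$encoding <- factor(df$encoding, levels = c("sigimg", "gadf", "mtf"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::facet_wrap(~encoding, ncol = 1, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
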