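#' Sliding-window specification
#'
#' Window length and stride are given in milliseconds and converted to sample
#' counts as `round(ms * fs / 1000)` when applied to a recording.  The
#' defaults (200 ms window, 100 ms stride) give 20-sample windows with a
#' 10-sample stride at the 100 Hz Ninapro DB1 rate, keeping per-decision
#' latency well under the 300 ms budget usual for myoelectric control.
#'
#' @param tw_ms Window length in milliseconds.
#' @param ts_ms Stride in milliseconds.
#' @return An object of class `window_spec`.
#' @examples
#' window_spec()                # 200 ms / 100 ms
#' window_samples(window_spec(), fs = 100)
#' @export
window_spec <- function(tw_ms = 200, ts_ms = 100) {
  if (!is.numeric(tw_ms) || tw_ms <= 0 || !is.numeric(ts_ms) || ts_ms <= 0) {
    abort("`tw_ms` and `ts_ms` must be positive.", class = "semg_config_error")
  }
  structure(list(tw_ms = as.numeric(tw_ms), ts_ms = as.numeric(ts_ms)),
            class = "window_spec")
}

#' @rdname window_spec
#' @param spec A `window_spec`.
#' @param fs Sampling rate in Hz.
#' @return For `window_samples()`, a list with integer elements `tw` and `ts`.
#' @export
window_samples <- function(spec, fs) {
  tw <- as.integer(round(spec$tw_ms * fs / 1000))
  ts <- as.integer(round(spec$ts_ms * fs / 1000))
  if (tw < 1L || ts < 1L) {
    abort(sprintf(
      "Window spec resolves to tw = %d, ts = %d samples at %g Hz; both must be >= 1.",
      tw, ts, fs), class = "semg_config_error")
  }
  list(tw = tw, ts = ts)
}

#' Segment a recording into labelled sliding windows
#'
#' Slides a fixed-length window along the recording at offsets
#' `0, ts, 2 ts, ...` and keeps only complete windows (a tail shorter than
#' the window is dropped, not padded).  Each window inherits the recording's
#' gesture label and provenance.
#'
#' @param rec An [semg_recording()].
#' @param spec A [window_spec()]; defaults to 200 ms / 100 ms.
#' @return A tibble with one row per window: `data` (list of tw-by-C
#'   matrices), `label`, `subject`, `repetition`, `start_index` (0-based
#'   sample offset).
#' @examples
#' rec <- semg_recording(matrix(runif(500 * 3), 500, 3), fs = 100,
#'                       stimulus = 5)
#' nrow(sliding_windows(rec))   # floor((500 - 20) / 10) + 1 = 49
#' @export
sliding_windows <- function(rec, spec = window_spec()) {
  assert_recording(rec)
  ws <- window_samples(spec, rec$fs)
  n <- nrow(rec$signal)
  n_win <- if (n >= ws$tw) (n - ws$tw) %/% ws$ts + 1L else 0L
  starts <- if (n_win > 0L) (seq_len(n_win) - 1L) * ws$ts else integer(0)
  tibble::tibble(
    data = lapply(starts, function(s) rec$signal[s + seq_len(ws$tw), , drop = FALSE]),
    label = rep(rec$stimulus, n_win),
    subject = rep(rec$subject, n_win),
    repetition = rep(rec$repetition, n_win),
    start_index = as.integer(starts)
  )
}

# ---- db4 wavelet denoising --------------------------------------------------
# No wavelet package ships with this stack, so the periodised discrete wavelet
# transform is implemented directly.  Filters are the standard orthonormal
# Daubechies family (dbK = K vanishing moments, 2K taps).

db_scaling_filters <- list(
  db1 = c(0.7071067811865476, 0.7071067811865476),
  db2 = c(0.48296291314469025, 0.836516303737469,
          0.22414386804185735, -0.12940952255092145),
  db3 = c(0.3326705529509569, 0.8068915093133388, 0.4598775021193313,
          -0.13501102001039084, -0.08544127388224149, 0.035226291882100656),
  db4 = c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
          -0.02798376941698385, -0.18703481171888114, 0.030841381835986965,
          0.032883011666982945, -0.010597401784997278)
)

wavelet_filters <- function(wavelet_name) {
  h <- db_scaling_filters[[wavelet_name]]
  if (is.null(h)) {
    abort(sprintf("Unknown wavelet '%s' (supported: %s).", wavelet_name,
                  paste(names(db_scaling_filters), collapse = ", ")),
          class = "semg_config_error")
  }
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror highpass
  list(h = h, g = g)
}

# one level of the periodised DWT; x must have even length
dwt_step <- function(x, f) {
  n <- length(x)
  L <- length(f$h)
  # y[k] = sum_l f[l] * x[(2k - 2 + l - 1) mod n + 1], k = 1..n/2
  idx <- outer(2 * (seq_len(n / 2) - 1), seq_len(L) - 1, "+") %% n + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(approx = drop(xm %*% f$h), detail = drop(xm %*% f$g))
}

idwt_step <- function(approx, detail, f) {
  n2 <- length(approx)
  n <- 2 * n2
  L <- length(f$h)
  x <- numeric(n)
  pos <- outer(2 * (seq_len(n2) - 1), seq_len(L) - 1, "+") %% n + 1
  for (l in seq_len(L)) {
    contrib <- approx * f$h[l] + detail * f$g[l]
    p <- pos[, l]
    x[p] <- x[p] + contrib
  }
  x
}

dwt_periodic <- function(x, f, level) {
  coeffs <- vector("list", level)
  pads <- integer(level)
  for (j in seq_len(level)) {
    pads[j] <- length(x) %% 2L
    if (pads[j]) x <- c(x, x[length(x)])
    st <- dwt_step(x, f)
    coeffs[[j]] <- st$detail
    x <- st$approx
  }
  list(approx = x, details = coeffs, pads = pads)
}

idwt_periodic <- function(dec, f) {
  x <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    x <- idwt_step(x, dec$details[[j]], f)
    if (dec$pads[j]) x <- x[-length(x)]
  }
  x
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Wavelet-denoise a recording
#'
#' Each channel is decomposed with a periodised discrete wavelet transform,
#' the detail coefficients are thresholded, and the channel is reconstructed
#' at its original length.  The default follows common sEMG practice: the db4
#' wavelet, four decomposition levels, and the soft universal (VisuShrink)
#' threshold \eqn{\sigma \sqrt{2 \log n}} with the noise scale \eqn{\sigma}
#' estimated per channel from the finest detail level by the median absolute
#' deviation divided by 0.6745.
#'
#' @param rec An [semg_recording()].
#' @param wavelet_name One of `"db1"`..`"db4"`.
#' @param level Decomposition depth; the signal must have at least
#'   `2^level` samples per channel.
#' @param threshold_rule `"soft"` (default) or `"hard"`.
#' @return A denoised `semg_recording` with the same shape and labels.
#' @export
wavelet_denoise <- function(rec, wavelet_name = "db4", level = 4L,
                            threshold_rule = c("soft", "hard")) {
  assert_recording(rec)
  threshold_rule <- match.arg(threshold_rule)
  f <- wavelet_filters(wavelet_name)
  n <- nrow(rec$signal)
  if (n < 2^level) {
    abort(sprintf("Signal length %d is too short for level %d (needs >= %d).",
                  n, level, 2^level), class = "semg_config_error")
  }
  out <- apply(rec$signal, 2L, function(x) {
    dec <- dwt_periodic(x, f, level)
    sigma <- mad(dec$details[[1]], center = 0, constant = 1) / 0.6745
    thr <- sigma * sqrt(2 * log(n))
    dec$details <- lapply(dec$details, function(d) {
      if (threshold_rule == "soft") soft_threshold(d, thr) else d * (abs(d) > thr)
    })
    idwt_periodic(dec, f)
  })
  rec$signal <- matrix(out, nrow = n)
  rec
}

# ---- anti-aliased integer decimation ---------------------------------------

# zero-phase windowed-sinc lowpass, reflect-padded at the edges
fir_lowpass <- function(x, cutoff, taps) {
  m <- (taps - 1) / 2
  k <- seq(-m, m)
  h <- 2 * cutoff * sinc(2 * cutoff * k) * hamming(taps)
  h <- h / sum(h)
  pad <- m
  xp <- c(rev(x[seq_len(pad) + 1]), x, rev(x[length(x) - seq_len(pad)]))
  drop(stats::filter(xp, h, sides = 2))[pad + seq_along(x)]
}

sinc <- function(t) ifelse(t == 0, 1, sin(pi * t) / (pi * t))
hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))

#' Downsample a recording to a lower sampling rate
#'
#' Applies a zero-phase anti-aliasing FIR lowpass (windowed sinc, cutoff at
#' 0.45 of the target Nyquist band) to each channel and then keeps every
#' `factor`-th sample, where `factor = fs / target_fs` must be an integer.
#' Output length is `ceiling(n / factor)`.  With `target_fs == fs` the
#' recording is returned unchanged.
#'
#' @param rec An [semg_recording()].
#' @param target_fs Target sampling rate in Hz; `rec$fs` must be an integer
#'   multiple of it.
#' @return An `semg_recording` at `target_fs`.
#' @examples
#' rec <- semg_recording(matrix(runif(2500 * 8), 2500, 8), fs = 500)
#' nrow(downsample_recording(rec, 100)$signal)   # 500
#' @export
downsample_recording <- function(rec, target_fs) {
  assert_recording(rec)
  if (target_fs <= 0) abort("`target_fs` must be positive.",
                            class = "semg_config_error")
  factor <- rec$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9) {
    abort(sprintf("fs = %g is not an integer multiple of target_fs = %g.",
                  rec$fs, target_fs), class = "semg_config_error")
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  n <- nrow(rec$signal)
  taps <- 8L * factor + 1L
  filtered <- apply(rec$signal, 2L, fir_lowpass, cutoff = 0.45 / factor,
                    taps = taps)
  keep <- seq(1L, n, by = factor)
  rec$signal <- matrix(filtered, nrow = n)[keep, , drop = FALSE]
  rec$fs <- target_fs
  rec
}
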