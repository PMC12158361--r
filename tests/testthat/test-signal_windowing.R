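test_that("window counts follow floor((n - tw)/ts) + 1 and slices are verbatim", {
  spec <- window_spec(200, 100)
  ws <- window_samples(spec, fs = 100)
  expect_equal(ws$tw, 20L)
  expect_equal(ws$ts, 10L)

  # brute-force enumeration over a grid of lengths and strides
  for (n in c(0, 5, 19, 20, 21, 57, 500)) {
    for (params in list(c(20, 10), c(20, 20), c(7, 3))) {
      tw <- params[1]; ts <- params[2]
      rec <- make_recording(n = max(n, 1), channels = 2, seed = n + tw)
      if (n == 0) rec$signal <- rec$signal[integer(0), , drop = FALSE]
      wins <- sliding_windows(rec, window_spec(tw * 10, ts * 10))
      starts <- c()
      s <- 0
      while (s + tw <= n) { starts <- c(starts, s); s <- s + ts }
      expect_equal(nrow(wins), length(starts))
      expect_equal(wins$start_index, as.integer(starts))
      for (i in seq_len(nrow(wins))) {
        expect_identical(wins$data[[i]],
                         rec$signal[wins$start_index[i] + seq_len(tw), ,
                                    drop = FALSE])
      }
    }
  }
})

test_that("a 500-sample 100 Hz recording yields 49 labelled windows", {
  rec <- make_recording(n = 500, channels = 10, stimulus = 7L,
                        subject = 3L, repetition = 2L)
  wins <- sliding_windows(rec)
  expect_equal(nrow(wins), 49L)
  expect_true(all(wins$label == 7L))
  expect_true(all(wins$subject == 3L))
  expect_true(all(wins$repetition == 2L))
  expect_equal(nrow(sliding_windows(make_recording(n = 10))), 0L)
})

test_that("degenerate window specs raise configuration errors", {
  expect_error(window_spec(0, 100), class = "semg_config_error")
  expect_error(window_samples(window_spec(2, 100), fs = 100),
               class = "semg_config_error")
})

test_that("wavelet denoising preserves zero, raises SNR, and contracts", {
  zero <- semg_recording(matrix(0, 128, 2), fs = 100)
  expect_equal(wavelet_denoise(zero)$signal, matrix(0, 128, 2))

  # clean sine + white noise; SNR must improve, averaged over 20 seeds
  n <- 256
  clean <- sin(2 * pi * 3 * seq_len(n) / n)
  snr <- function(x) 10 * log10(sum(clean^2) / sum((x - clean)^2))
  gains <- vapply(1:20, function(s) {
    set.seed(s)
    noisy <- clean + rnorm(n, sd = 0.2)
    den <- wavelet_denoise(semg_recording(noisy, fs = 100))$signal[, 1]
    snr(den) - snr(noisy)
  }, numeric(1))
  expect_gt(mean(gains), 0)

  # a second pass changes the signal less than the first
  set.seed(1)
  noisy <- semg_recording(clean + rnorm(n, sd = 0.2), fs = 100)
  once <- wavelet_denoise(noisy)
  twice <- wavelet_denoise(once)
  d1 <- mean(abs(once$signal - noisy$signal))
  d2 <- mean(abs(twice$signal - once$signal))
  expect_lt(d2, d1)
})

test_that("the periodised DWT reconstructs perfectly without thresholding", {
  ns <- asNamespace("semgimage")
  for (wav in c("db1", "db2", "db4")) {
    f <- ns$wavelet_filters(wav)
    set.seed(3)
    x <- rnorm(96)   # not a power of two: exercises odd-length padding
    dec <- ns$dwt_periodic(x, f, 4L)
    expect_equal(ns$idwt_periodic(dec, f), x, tolerance = 1e-10)
  }
})

test_that("wavelet denoising rejects bad configurations", {
  rec <- make_recording(n = 64)
  expect_error(wavelet_denoise(rec, "db9"), class = "semg_config_error")
  expect_error(wavelet_denoise(make_recording(n = 8), level = 4),
               class = "semg_config_error")
})

test_that("downsampling decimates with anti-aliasing and preserves constants", {
  rec <- make_recording(n = 2500, channels = 8, fs = 500)
  down <- downsample_recording(rec, 100)
  expect_equal(nrow(down$signal), 500L)
  expect_equal(down$fs, 100)

  same <- downsample_recording(rec, 500)
  expect_identical(same$signal, rec$signal)

  const <- semg_recording(matrix(2.5, 1000, 2), fs = 500)
  dc <- downsample_recording(const, 100)
  interior <- dc$signal[10:190, ]
  expect_lt(max(abs(interior - 2.5)), 1e-6)

  expect_error(downsample_recording(rec, 300), class = "semg_config_error")
})

test_that("denoising and downsampling commute with channel permutation", {
  rec <- make_recording(n = 500, channels = 4, fs = 500, seed = 9)
  perm <- c(3, 1, 4, 2)
  permute <- function(r) { r$signal <- r$signal[, perm]; r }
  for (op in list(function(r) wavelet_denoise(r, level = 3),
                  function(r) downsample_recording(r, 100))) {
    expect_equal(op(permute(rec))$signal, permute(op(rec))$signal)
  }
})
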