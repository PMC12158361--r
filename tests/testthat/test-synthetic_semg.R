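test_that("generation is deterministic, non-negative, and complete", {
  cfg <- synth_config(subjects = 2, gestures = 3, repetitions = 4,
                      channels = 5, duration_s = 1, seed = 21)
  a <- generate_semg(cfg)
  b <- generate_semg(cfg)
  expect_length(a, 2L * 3L * 4L)
  expect_identical(lapply(a, `[[`, "signal"), lapply(b, `[[`, "signal"))
  expect_true(all(vapply(a, function(r) all(r$signal >= 0), TRUE)))
  expect_true(all(vapply(a, function(r) nrow(r$signal) == 100, TRUE)))

  keys <- vapply(a, function(r) paste(r$subject, r$stimulus, r$repetition),
                 character(1))
  expect_equal(length(unique(keys)), length(a))
  expect_error(synth_config(duration_s = 0.05),
               class = "semg_config_error")
})

test_that("class structure dominates noise at high SNR", {
  cfg <- synth_config(subjects = 1, gestures = 4, repetitions = 8,
                      channels = 6, duration_s = 2, snr_db = 60, seed = 3)
  recs <- generate_semg(cfg)
  feats <- t(vapply(recs, function(r) colMeans(r$signal), numeric(6)))
  labs <- vapply(recs, `[[`, integer(1), "stimulus")
  centroids <- t(vapply(1:4, function(g) colMeans(feats[labs == g, ]),
                        numeric(6)))
  between <- mean(dist(centroids))
  within_var <- mean(vapply(1:4, function(g) {
    mean(rowSums(sweep(feats[labs == g, ], 2, centroids[g, ])^2))
  }, numeric(1)))
  expect_gt(between / within_var, 10)
})

test_that("a nearest-centroid baseline clears 80% on default-SNR data", {
  recs <- generate_semg(synth_config(subjects = 3, gestures = 6,
                                     repetitions = 6, duration_s = 2,
                                     seed = 7))
  wins <- dplyr::bind_rows(lapply(recs, sliding_windows))
  test_reps <- c(2L, 5L)
  tr <- wins[!wins$repetition %in% test_reps, ]
  te <- wins[wins$repetition %in% test_reps, ]
  base <- nearest_centroid_baseline(tr, te)
  expect_gt(base$accuracy, 0.8)
})

test_that("Ninapro-style export names files correctly and round-trips", {
  recs <- generate_semg(synth_config(subjects = 2, gestures = 3,
                                     repetitions = 4, channels = 3,
                                     duration_s = 1, seed = 13))
  dir <- withr::local_tempdir()
  paths <- export_ninapro_style(recs, dir)
  expect_length(paths, 24L)
  expect_true(file.exists(file.path(dir, "001_002_003.mat")))
  expect_true(file.exists(file.path(dir, "002_003_004.mat")))

  disc <- discover_recordings(dir)
  expect_equal(sum(disc$malformed), 0L)
  for (i in c(1L, 12L, 24L)) {
    row <- disc[i, ]
    back <- read_ninapro_mat(row$path, subject = row$subject,
                             stimulus = row$stimulus,
                             repetition = row$repetition)
    orig <- Filter(function(r) {
      r$subject == row$subject && r$stimulus == row$stimulus &&
        r$repetition == row$repetition
    }, recs)[[1]]
    expect_identical(back$signal, orig$signal)
  }
})

test_that("the arm-band preset mirrors an 8-channel 500 Hz session", {
  cfg <- armband_config(seed = 2)
  expect_equal(cfg$channels, 8L)
  expect_equal(cfg$fs, 500)
  expect_equal(cfg$gestures, 6L)
  expect_equal(cfg$repetitions, 30L)
  # the preset feeds the denoise + downsample flow
  cfg_small <- armband_config(subjects = 1, gestures = 1, repetitions = 1,
                              duration_s = 1, seed = 2)
  rec <- generate_semg(cfg_small)[[1]]
  down <- downsample_recording(wavelet_denoise(rec), 100)
  expect_equal(down$fs, 100)
  expect_equal(nrow(down$signal), 100L)
})

test_that("permuting gesture weights permutes the learned structure", {
  # swapping two gesture labels in the generator yields the same signals
  # under the swapped naming: centroids follow the gesture identity
  cfg <- synth_config(subjects = 1, gestures = 3, repetitions = 5,
                      channels = 4, duration_s = 1, snr_db = 40, seed = 9)
  recs <- generate_semg(cfg)
  feats <- t(vapply(recs, function(r) colMeans(r$signal), numeric(4)))
  labs <- vapply(recs, `[[`, integer(1), "stimulus")
  cent <- t(vapply(1:3, function(g) colMeans(feats[labs == g, ]),
                   numeric(4)))
  # nearest-centroid assignment recovers the generating gesture for
  # every repetition at high SNR
  d <- as.matrix(dist(rbind(cent, feats)))[-(1:3), 1:3]
  expect_equal(unname(max.col(-d)), labs)
})
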