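test_that("unit rescaling maps extremes to +/-1 and handles degenerate input", {
  expect_equal(rescale_unit(c(0, 5, 10)), c(-1, 0, 1))
  x <- runif(50)
  r <- rescale_unit(x)
  expect_equal(r[which.max(x)], 1)
  expect_equal(r[which.min(x)], -1)
  expect_true(all(abs(r) <= 1))
  expect_equal(rescale_unit(c(3, 3, 3)), c(0, 0, 0))
  expect_error(rescale_unit(numeric(0)))
})

test_that("polar mapping gives angles in [0, pi] and timestamp radii", {
  p <- to_polar(c(-1, 0, 1))
  expect_equal(p$angles, c(pi, pi / 2, 0))
  expect_equal(to_polar(rep(0, 4))$radii, c(0.25, 0.5, 0.75, 1))
  # clipping guards acos against roundoff just outside [-1, 1]
  expect_equal(to_polar(c(1 + 1e-13, -1 - 1e-13))$angles, c(0, pi))
  expect_error(to_polar(c(0, 1.5)))
})

test_that("GADF matches the hand example and a brute-force double loop", {
  g <- gadf_matrix(to_polar(rescale_unit(c(0, 5, 10)))$angles)
  expect_equal(g, rbind(c(1, 0, -1), c(0, 1, 0), c(-1, 0, 1)),
               tolerance = 1e-14)

  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(2:64, 1)
    x <- rnorm(n)
    ang <- to_polar(rescale_unit(x))$angles
    fast <- gadf_matrix(ang)
    slow <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      slow[i, j] <- cos(ang[i] - ang[j])
    }
    expect_lt(max(abs(fast - slow)), 1e-12)
  }
  # structural invariants
  set.seed(5)
  ang <- to_polar(rescale_unit(rnorm(30)))$angles
  g <- gadf_matrix(ang)
  expect_equal(diag(g), rep(1, 30))
  expect_equal(g, t(g))
  s <- gadf_matrix(ang, formula = "sin_diff")
  expect_equal(s, -t(s))
  expect_equal(diag(s), rep(0, 30))
})

test_that("quantile binning is total, ordered, and collapses constants", {
  expect_equal(mtf_bins(c(1, 2, 1, 2), Q = 2)$bins, c(0L, 1L, 0L, 1L))
  expect_equal(length(unique(mtf_bins(rep(4, 10), Q = 8)$bins)), 1L)
  for (seed in 1:20) {
    set.seed(seed)
    b <- mtf_bins(rnorm(40), Q = 8)
    expect_true(all(b$bins >= 0L & b$bins <= 7L))
    expect_equal(length(b$bins), 40L)
    expect_equal(length(b$bin_edges), 9L)
    expect_true(!is.unsorted(b$bin_edges))
  }
  expect_error(mtf_bins(1:10, Q = 1), class = "semg_config_error")
  expect_error(mtf_bins(1, Q = 2))
})

test_that("transition matrices match hand enumeration and are row-stochastic", {
  expect_equal(mtf_transition(c(0L, 1L, 0L, 1L), Q = 2),
               rbind(c(0, 1), c(1, 0)))
  # constant bins: that row is a self-loop, empty rows become uniform
  W <- mtf_transition(rep(2L, 6), Q = 4)
  expect_equal(W[3, ], c(0, 0, 1, 0))
  expect_equal(W[1, ], rep(0.25, 4))

  for (Q in c(2, 4, 8, 16)) {
    for (seed in 1:25) {
      set.seed(seed * Q)
      x <- rnorm(sample(2:80, 1))
      W <- mtf_transition(mtf_bins(x, Q), Q)
      expect_equal(rowSums(W), rep(1, Q), tolerance = 1e-9)
      expect_true(all(W >= 0))
    }
  }
})

test_that("the Markov field matches direct substitution and a brute-force loop", {
  bins <- c(0L, 1L, 0L, 1L)
  W <- rbind(c(0, 1), c(1, 0))
  expect_equal(mtf_field(bins, W),
               rbind(c(0, 1, 0, 1), c(1, 0, 1, 0), c(0, 1, 0, 1),
                     c(1, 0, 1, 0)))

  for (seed in 1:50) {
    set.seed(seed)
    n <- sample(2:64, 1)
    Q <- sample(c(2, 4, 8), 1)
    b <- mtf_bins(rnorm(n), Q)$bins
    W <- mtf_transition(b, Q)
    fast <- mtf_field(b, W)
    slow <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      slow[i, j] <- W[b[i] + 1L, b[j] + 1L]
    }
    expect_identical(fast, slow)
  }
  # constant series: every entry equals the single self-transition
  b <- mtf_bins(rep(1, 5), Q = 4)$bins
  M <- mtf_field(b, mtf_transition(b, 4))
  expect_equal(unique(as.vector(M)), 1)
})

test_that("the channel rearrangement tiles all pairs adjacently", {
  w <- matrix(runif(200), 20, 10)
  s <- sigimg(w)
  expect_equal(dim(s), c(20L, 100L))
  expect_identical(s[, 1:10], w)               # block 0 is the original
  expect_identical(sigimg(w[, 1, drop = FALSE]), w[, 1, drop = FALSE])

  # every original column appears exactly C times
  for (c in 1:10) {
    matches <- sum(apply(s, 2, function(col) identical(col, w[, c])))
    expect_equal(matches, 10L)
  }

  # every unordered channel pair is column-adjacent in some block (C = 3)
  w3 <- matrix(seq_len(30), 10, 3)
  s3 <- sigimg(w3)
  col_id <- apply(s3, 2, function(col) {
    which(vapply(1:3, function(c) identical(col, w3[, c]), TRUE))
  })
  adjacent <- unique(t(apply(cbind(col_id[-length(col_id)], col_id[-1]),
                             1, sort)))
  pairs <- t(utils::combn(3, 2))
  for (k in seq_len(nrow(pairs))) {
    expect_true(any(adjacent[, 1] == pairs[k, 1] &
                      adjacent[, 2] == pairs[k, 2]))
  }
})

test_that("subimage stitching preserves order and rejects mismatches", {
  subs <- replicate(10, matrix(runif(400), 20, 20), simplify = FALSE)
  big <- stitch_subimages(subs)
  expect_equal(dim(big), c(20L, 200L))
  for (c in 1:10) {
    expect_identical(big[, (c - 1) * 20 + 1:20], subs[[c]])
  }
  expect_identical(stitch_subimages(subs[1]), subs[[1]])
  halves <- stitch_subimages(list(matrix(1, 3, 3), matrix(2, 3, 3)))
  expect_true(all(halves[, 1:3] == 1) && all(halves[, 4:6] == 2))
  expect_error(stitch_subimages(list(matrix(1, 3, 3), matrix(1, 4, 4))))
})

test_that("window encoding produces normalized triple-image samples", {
  set.seed(2)
  w <- matrix(runif(200), 20, 10)
  enc <- encode_window(w)
  expect_s3_class(enc, "encoded_sample")
  expect_equal(dim(enc$sigimg), c(20L, 100L))
  expect_equal(dim(enc$gadf), c(20L, 200L))
  expect_equal(dim(enc$mtf), c(20L, 200L))
  for (nm in c("sigimg", "gadf", "mtf")) {
    expect_equal(range(enc[[nm]]), c(0, 1))
  }
  expect_identical(encode_window(w), enc)   # deterministic

  # GADF/MTF are invariant to positive affine transforms of the window
  enc2 <- encode_window(2.7 * w + 11)
  expect_equal(enc2$gadf, enc$gadf, tolerance = 1e-9)
  expect_equal(enc2$mtf, enc$mtf, tolerance = 1e-9)

  # reversing channel order reverses the stitched block order
  encr <- encode_window(w[, 10:1])
  blocks <- function(m) lapply(1:10, function(c) m[, (c - 1) * 20 + 1:20])
  expect_equal(blocks(encr$gadf), rev(blocks(enc$gadf)), tolerance = 1e-12)
  expect_equal(blocks(encr$mtf), rev(blocks(enc$mtf)), tolerance = 1e-12)
})

test_that("encode_windows augments a window table with image columns", {
  rec <- make_recording(n = 60, channels = 3, stimulus = 4L)
  tbl <- encode_windows(sliding_windows(rec), Q = 4)
  expect_true(all(c("sigimg", "gadf", "mtf") %in% names(tbl)))
  expect_equal(dim(tbl$sigimg[[1]]), c(20L, 9L))
  expect_equal(dim(tbl$gadf[[1]]), c(20L, 60L))
})
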