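test_that("the three-stream spec reproduces the reference layer shapes", {
  spec <- mscnn_spec(52)
  tr1 <- trace_branch(spec$branches$sigimg)
  expect_equal(tr1$out_h, c(20L, 10L, 10L, 5L))
  expect_equal(tr1$out_w, c(100L, 50L, 50L, 25L))
  expect_equal(tr1$out_c, c(16L, 16L, 32L, 32L))
  expect_equal(spec$branches$sigimg$flatten_size, 4000L)

  for (s in c("gadf", "mtf")) {
    tr <- trace_branch(spec$branches[[s]])
    expect_equal(tr$out_h, c(20L, 10L, 10L, 5L))
    expect_equal(tr$out_w, c(200L, 100L, 100L, 50L))
    expect_equal(tr$out_c, c(16L, 16L, 32L, 32L))
    expect_equal(spec$branches[[s]]$flatten_size, 8000L)
  }
  concat <- sum(vapply(spec$branches, function(b) b$flatten_size,
                       integer(1)))
  expect_equal(concat, 20000L)
  expect_equal(spec$fusion_fc, c(4096L, 2048L, 52L))
  expect_equal(spec$dropout_rate, 0.5)
  expect_true(spec$batchnorm)
  expect_error(mscnn_spec(1), class = "semg_config_error")
})

test_that("single- and dual-stream specs follow the ablation layouts", {
  sig <- sscnn_spec("sigimg", 52)
  expect_equal(sig$fusion_fc, c(1024L, 256L, 52L))
  expect_equal(sig$branches$sigimg$flatten_size, 4000L)

  gadf <- sscnn_spec("gadf", 52)
  mtf <- sscnn_spec("mtf", 52)
  expect_equal(gadf$fusion_fc, c(2048L, 512L, 52L))
  expect_equal(gadf$branches$gadf$layers, mtf$branches$mtf$layers)
  expect_equal(sscnn_spec("mtf", 6)$fusion_fc[3], 6L)
  expect_error(sscnn_spec("raw", 52), class = "semg_config_error")

  d1 <- dscnn_spec(c("sigimg", "gadf"), 52)
  expect_equal(sum(vapply(d1$branches, function(b) b$flatten_size,
                          integer(1))), 12000L)
  d2 <- dscnn_spec(c("gadf", "mtf"), 52)
  expect_equal(sum(vapply(d2$branches, function(b) b$flatten_size,
                          integer(1))), 16000L)
  expect_equal(d1$fusion_fc, c(4096L, 1024L, 52L))
  expect_error(dscnn_spec(c("sigimg", "mtf"), 52),
               class = "semg_config_error")
})

test_that("MAC counting follows the conv/FC convention and is additive", {
  # toy conv: 4x4x2 output from a 3x3x1 kernel -> 4*4*2*3*3*1 = 288
  ns <- asNamespace("semgimage")
  toy_branch <- ns$new_branch_spec(c(4L, 4L, 1L),
                                   list(ns$conv_layer(2L, c(3L, 3L),
                                                      pad = 1L)))
  toy <- ns$new_model_spec("toy", list(sigimg = toy_branch),
                           integer(0), 2L)
  flat <- toy_branch$flatten_size
  expect_equal(count_macs(toy), 288 + flat * 2)

  # independent arithmetic oracle for the full three-stream model
  conv_macs <- function(oh, ow, oc, kh, kw, ic) oh * ow * oc * kh * kw * ic
  b1 <- conv_macs(20, 100, 16, 3, 3, 1) + conv_macs(10, 50, 32, 3, 3, 16)
  b23 <- conv_macs(20, 200, 16, 3, 3, 1) + conv_macs(10, 100, 32, 5, 5, 16)
  fc <- 20000 * 4096 + 4096 * 2048 + 2048 * 52
  expect_equal(count_macs(mscnn_spec(52)), b1 + 2 * b23 + fc)

  # ordering: three streams > each dual > each single
  m <- count_macs(mscnn_spec(52))
  d <- vapply(list(c("sigimg", "gadf"), c("gadf", "mtf")),
              function(s) count_macs(dscnn_spec(s, 52)), numeric(1))
  s <- vapply(c("sigimg", "gadf", "mtf"),
              function(x) count_macs(sscnn_spec(x, 52)), numeric(1))
  expect_true(all(m > d))
  expect_true(all(outer(d, s, ">")))
})

test_that("forward passes give finite softmax probability vectors", {
  sets <- tiny_sets()
  spec <- tiny_spec()
  ns <- asNamespace("semgimage")
  set.seed(1)
  net <- ns$init_network(spec)
  idx <- 1:8
  inputs <- ns$dataset_inputs(sets$train, spec$streams, idx)
  fwd <- ns$network_forward(net, inputs, train = FALSE)
  probs <- ns$softmax_probs(fwd$logits)
  expect_true(all(is.finite(probs)))
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 8), tolerance = 1e-6)

  # zero input is also finite
  zero_in <- lapply(inputs, function(m) m * 0)
  fz <- ns$network_forward(net, zero_in, train = FALSE)
  expect_true(all(is.finite(fz$logits)))
})

test_that("a single small-step update decreases the batch loss (5 seeds)", {
  sets <- tiny_sets()
  spec <- tiny_spec()
  ns <- asNamespace("semgimage")
  idx <- 1:32
  inputs <- ns$dataset_inputs(sets$train, spec$streams, idx)
  labels <- sets$train$labels[idx]
  for (seed in 1:5) {
    set.seed(seed)
    net <- ns$init_network(spec)
    state <- list(t = 0L, m = ns$zeros_like_tree(net$par),
                  v = ns$zeros_like_tree(net$par))
    fwd0 <- ns$network_forward(net, inputs, train = TRUE, dropout = 0)
    loss0 <- ns$network_backward(net, fwd0, labels)$loss
    step <- ns$network_train_step(net, state, inputs, labels,
                                  lr = 1e-4, dropout = 0)
    fwd1 <- ns$network_forward(step$net, inputs, train = TRUE, dropout = 0)
    loss1 <- ns$network_backward(step$net, fwd1, labels)$loss
    expect_lt(loss1, loss0)
  }
})

test_that("training rejects datasets whose shapes mismatch the spec", {
  sets <- tiny_sets()
  wrong <- mscnn_spec(2)   # expects 10-channel image widths
  expect_error(train(wrong, sets$train, quick_config()),
               class = "semg_config_error")
})
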