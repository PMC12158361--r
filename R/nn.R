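# CNN engine.  Feature-map batches are (N*H*W) x C matrices with row index
# (n-1)*H*W + (w-1)*H + h (see src/convops.cpp); convolutions run as
# im2col + BLAS gemm, so the heavy lifting is dgemm.  Everything is plain
# numeric matrices so training is reproducible from a single seed.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# per-layer static shape metadata for one branch
branch_meta <- function(branch) {
  h <- branch$input_shape[1]; w <- branch$input_shape[2]
  c <- branch$input_shape[3]
  lapply(branch$layers, function(ly) {
    if (ly$type == "conv") {
      oh <- h + 2L * ly$pad - ly$kernel[1] + 1L
      ow <- w + 2L * ly$pad - ly$kernel[2] + 1L
      m <- list(type = "conv", kh = ly$kernel[1], kw = ly$kernel[2],
                pad = ly$pad, inH = h, inW = w, inC = c,
                outH = oh, outW = ow, outC = ly$filters)
      h <<- oh; w <<- ow; c <<- ly$filters
    } else {
      m <- list(type = "maxpool", inH = h, inW = w, inC = c,
                outH = h %/% 2L, outW = w %/% 2L, outC = c)
      h <<- h %/% 2L; w <<- w %/% 2L
    }
    m
  })
}

# He (fan-in) initialisation; draws come from the current RNG stream
init_network <- function(spec) {
  par <- list(branches = list(), fc = list())
  bn <- list(branches = list())
  meta <- list(branches = list())
  for (s in names(spec$branches)) {
    m <- branch_meta(spec$branches[[s]])
    meta$branches[[s]] <- m
    par$branches[[s]] <- lapply(m, function(ly) {
      if (ly$type != "conv") return(list())
      fan_in <- ly$kh * ly$kw * ly$inC
      p <- list(W = matrix(rnorm(fan_in * ly$outC, sd = sqrt(2 / fan_in)),
                           fan_in, ly$outC))
      if (spec$batchnorm) {
        p$gamma <- rep(1, ly$outC)
        p$beta <- rep(0, ly$outC)
      } else {
        p$b <- rep(0, ly$outC)
      }
      p
    })
    bn$branches[[s]] <- lapply(m, function(ly) {
      if (ly$type == "conv" && spec$batchnorm) {
        list(mean = rep(0, ly$outC), var = rep(1, ly$outC))
      } else list()
    })
  }
  fan_in <- sum(vapply(spec$branches, function(b) b$flatten_size, integer(1)))
  for (i in seq_along(spec$fusion_fc)) {
    out <- spec$fusion_fc[i]
    par$fc[[i]] <- list(
      W = matrix(rnorm(fan_in * out, sd = sqrt(2 / fan_in)), fan_in, out),
      b = rep(0, out))
    fan_in <- out
  }
  list(spec = spec, par = par, bn = bn, meta = meta)
}

rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# flatten (N*H*W) x C activations to N x (H*W*C) feature rows and back
flatten_act <- function(act, N, hw, C) {
  a <- array(act, dim = c(hw, N, C))
  matrix(aperm(a, c(1, 3, 2)), ncol = N) |> t()
}
unflatten_act <- function(flat, N, hw, C) {
  a <- array(t(flat), dim = c(hw, C, N))
  matrix(aperm(a, c(1, 3, 2)), ncol = C)
}

branch_forward <- function(lpar, lbn, lmeta, X, train) {
  N <- nrow(X)
  act <- matrix(as.vector(t(X)), ncol = 1L)
  caches <- vector("list", length(lmeta))
  new_bn <- lbn
  for (i in seq_along(lmeta)) {
    m <- lmeta[[i]]
    if (m$type == "conv") {
      col <- nn_im2col(act, N, m$inH, m$inW, m$inC, m$kh, m$kw, m$pad)
      z <- col %*% lpar[[i]]$W
      cache <- list(col = col)
      if (!is.null(lpar[[i]]$gamma)) {
        if (train) {
          mom <- nn_col_moments(z)
          mu <- mom$mean
          va <- mom$var
          new_bn[[i]]$mean <- BN_MOMENTUM * lbn[[i]]$mean + (1 - BN_MOMENTUM) * mu
          new_bn[[i]]$var <- BN_MOMENTUM * lbn[[i]]$var + (1 - BN_MOMENTUM) * va
        } else {
          mu <- lbn[[i]]$mean
          va <- lbn[[i]]$var
        }
        inv_sd <- 1 / sqrt(va + BN_EPS)
        r <- nn_bn_relu_forward(z, mu, inv_sd, lpar[[i]]$gamma,
                                lpar[[i]]$beta)
        act <- r$act
        cache$zhat <- r$zhat
        cache$inv_sd <- inv_sd
      } else {
        act <- pmax(z + rep_row(lpar[[i]]$b, nrow(z)), 0)
      }
      cache$act <- act
      caches[[i]] <- cache
    } else {
      res <- nn_maxpool(act, N, m$inH, m$inW, m$inC)
      act <- res$out
      caches[[i]] <- list(idx = res$idx)
    }
  }
  last <- lmeta[[length(lmeta)]]
  flat <- flatten_act(act, N, last$outH * last$outW, last$outC)
  list(flat = flat, caches = caches, bn = new_bn, N = N)
}

branch_backward <- function(lpar, lmeta, fwd, dflat) {
  N <- fwd$N
  last <- lmeta[[length(lmeta)]]
  dact <- unflatten_act(dflat, N, last$outH * last$outW, last$outC)
  grads <- vector("list", length(lmeta))
  for (i in rev(seq_along(lmeta))) {
    m <- lmeta[[i]]
    cache <- fwd$caches[[i]]
    if (m$type == "conv") {
      g <- list()
      if (!is.null(lpar[[i]]$gamma)) {
        r <- nn_bn_relu_backward(dact, cache$act, cache$zhat, cache$inv_sd,
                                 lpar[[i]]$gamma)
        g$gamma <- r$dgamma
        g$beta <- r$dbeta
        dz <- r$dz
      } else {
        dz <- dact * (cache$act > 0)
        g$b <- colSums(dz)
      }
      g$W <- crossprod(cache$col, dz)
      grads[[i]] <- g
      dcol <- tcrossprod(dz, lpar[[i]]$W)
      dact <- nn_col2im(dcol, N, m$inH, m$inW, m$inC, m$kh, m$kw, m$pad)
    } else {
      grads[[i]] <- list()
      dact <- nn_maxpool_backward(dact, cache$idx, N, m$inH, m$inW, m$inC)
    }
  }
  grads
}

# full forward pass; inputs is a named list of N x (H*W) matrices per stream
network_forward <- function(net, inputs, train = FALSE, dropout = 0) {
  spec <- net$spec
  bfwd <- list()
  for (s in spec$streams) {
    bfwd[[s]] <- branch_forward(net$par$branches[[s]], net$bn$branches[[s]],
                                net$meta$branches[[s]], inputs[[s]], train)
  }
  X <- do.call(cbind, lapply(bfwd, `[[`, "flat"))
  fc_caches <- vector("list", length(net$par$fc))
  nl <- length(net$par$fc)
  for (i in seq_len(nl)) {
    mask <- NULL
    if (train && dropout > 0) {
      mask <- matrix((runif(length(X)) >= dropout) / (1 - dropout),
                     nrow(X), ncol(X))
      X <- X * mask
    }
    z <- X %*% net$par$fc[[i]]$W + rep_row(net$par$fc[[i]]$b, nrow(X))
    fc_caches[[i]] <- list(input = X, mask = mask)
    X <- if (i < nl) pmax(z, 0) else z
    fc_caches[[i]]$out <- X
  }
  list(logits = X, bfwd = bfwd, fc_caches = fc_caches)
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# cross-entropy loss and full gradient tree for one batch
network_backward <- function(net, fwd, labels) {
  N <- nrow(fwd$logits)
  probs <- softmax_probs(fwd$logits)
  ll <- -mean(log(pmax(probs[cbind(seq_len(N), labels + 1L)], 1e-300)))
  dz <- probs
  dz[cbind(seq_len(N), labels + 1L)] <- dz[cbind(seq_len(N), labels + 1L)] - 1
  dz <- dz / N
  grads <- list(branches = list(), fc = vector("list", length(net$par$fc)))
  for (i in rev(seq_along(net$par$fc))) {
    cache <- fwd$fc_caches[[i]]
    grads$fc[[i]] <- list(W = crossprod(cache$input, dz),
                          b = colSums(dz))
    dX <- tcrossprod(dz, net$par$fc[[i]]$W)
    if (!is.null(cache$mask)) dX <- dX * cache$mask
    if (i > 1L) {
      prev_out <- fwd$fc_caches[[i - 1L]]$out
      dz <- dX * (prev_out > 0)
    } else {
      dflat <- dX
    }
  }
  sizes <- vapply(net$spec$streams, function(s) {
    net$spec$branches[[s]]$flatten_size
  }, integer(1))
  offset <- 0L
  for (s in net$spec$streams) {
    cols <- offset + seq_len(sizes[[s]])
    grads$branches[[s]] <- branch_backward(
      net$par$branches[[s]], net$meta$branches[[s]], fwd$bfwd[[s]],
      dflat[, cols, drop = FALSE])
    offset <- offset + sizes[[s]]
  }
  list(loss = ll, grads = grads, probs = probs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Adam over nested parameter/gradient trees -----------------------------

zeros_like_tree <- function(p) {
  if (is.list(p)) lapply(p, zeros_like_tree) else p * 0
}

# in-place Adam over the nested parameter tree (leaves are updated through
# nn_adam_leaf without copying; m and v are mutated alongside)
adam_update_tree <- function(par, grad, m, v, lr, t) {
  if (is.list(par)) {
    keys <- if (is.null(names(par))) seq_along(par) else names(par)
    for (k in keys) adam_update_tree(par[[k]], grad[[k]], m[[k]], v[[k]],
                                     lr, t)
  } else {
    nn_adam_leaf(par, grad, m, v, lr, t, 0.9, 0.999, 1e-8)
  }
  invisible(NULL)
}

# one optimisation step on a batch; parameters are updated in place
network_train_step <- function(net, state, inputs, labels, lr, dropout) {
  fwd <- network_forward(net, inputs, train = TRUE, dropout = dropout)
  for (s in net$spec$streams) net$bn$branches[[s]] <- fwd$bfwd[[s]]$bn
  bwd <- network_backward(net, fwd, labels)
  state$t <- state$t + 1L
  adam_update_tree(net$par, bwd$grads, state$m, state$v, lr, state$t)
  pred <- max.col(fwd$logits) - 1L
  list(net = net, state = state, loss = bwd$loss,
       acc = mean(pred == labels))
}

# extract the stream inputs for a row subset of a dataset
dataset_inputs <- function(dataset, streams, idx = NULL) {
  out <- list()
  for (s in streams) {
    m <- dataset$images[[s]]
    out[[s]] <- if (is.null(idx)) m else m[idx, , drop = FALSE]
  }
  out
}

network_predict <- function(net, dataset, batch_size = 200L) {
  n <- n_samples(dataset)
  probs <- matrix(NA_real_, n, net$spec$class_count)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    fwd <- network_forward(net, dataset_inputs(dataset, net$spec$streams, idx),
                           train = FALSE)
    probs[idx, ] <- softmax_probs(fwd$logits)
  }
  probs
}
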