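# A compact dense/convolutional network engine: explicit forward caches
# and analytic backward passes, so gradients at any intermediate
# activation (needed for class-activation mapping) are available. Data
# layouts: matrices (batch x features) for dense layers, arrays
# (H, W, C, B) for convolutional ones.

## ---- layer constructors ---------------------------------------------

nn_linear <- function(d_in, d_out) {
  list(type = "linear", d_in = d_in, d_out = d_out,
       W = matrix(stats::rnorm(d_in * d_out, 0, sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

nn_batchnorm <- function(d, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", d = d, gamma = rep(1, d), beta = numeric(d),
       run_mean = numeric(d), run_var = rep(1, d),
       momentum = momentum, eps = eps)
}

nn_relu <- function() list(type = "relu")

nn_dropout <- function(p) list(type = "dropout", p = p)

nn_conv <- function(k, c_in, c_out, stride = 1L, pad = 1L) {
  fan_in <- k * k * c_in
  list(type = "conv", k = k, c_in = c_in, c_out = c_out,
       stride = as.integer(stride), pad = as.integer(pad),
       W = matrix(stats::rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)),
                  fan_in, c_out),
       b = numeric(c_out))
}

nn_maxpool <- function() list(type = "maxpool")

nn_gap <- function() list(type = "gap")

## ---- conv plumbing ---------------------------------------------------

# Column-index matrix for im2col on a padded (Hp, Wp, C) volume with a
# k x k kernel and given stride; rows ordered spatial-position-first
# (h fastest), columns ordered (kh, kw, c).
im2col_index <- function(hp, wp, c, k, stride) {
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  base_r <- rep((seq_len(ho) - 1L) * stride, times = wo)
  base_c <- rep((seq_len(wo) - 1L) * stride, each = ho)
  off_r <- rep(seq_len(k), times = k)
  off_c <- rep(seq_len(k), each = k)
  idx <- matrix(0L, ho * wo, k * k * c)
  col <- 0L
  plane <- hp * wp
  for (ci in seq_len(c)) {
    for (j in seq_len(k * k)) {
      col <- col + 1L
      idx[, col] <- (base_r + off_r[j]) + (base_c + off_c[j] - 1L) * hp +
        (ci - 1L) * plane
    }
  }
  list(idx = idx, ho = ho, wo = wo)
}

pad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  out
}

conv_forward <- function(layer, x) {
  d <- dim(x)  # H, W, C, B
  xp <- pad_array(x, layer$pad)
  dp <- dim(xp)
  key <- paste(dp[1], dp[2], dp[3], layer$k, layer$stride, sep = "-")
  ii <- im2col_index(dp[1], dp[2], dp[3], layer$k, layer$stride)
  P <- nrow(ii$idx)
  B <- d[4]
  plane <- dp[1] * dp[2] * dp[3]
  # batch-expanded gather indices: rows (p, b) with p fastest
  big_idx <- ii$idx[rep(seq_len(P), times = B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * plane, each = P)
  col <- matrix(xp[big_idx], nrow = P * B)
  out_mat <- sweep(col %*% layer$W, 2, layer$b, "+")
  out <- array(out_mat, dim = c(ii$ho, ii$wo, B, layer$c_out))
  out <- aperm(out, c(1, 2, 4, 3))
  list(out = out, cache = list(col = col, big_idx = big_idx, dp = dp,
                               d = d, ho = ii$ho, wo = ii$wo))
}

conv_backward <- function(layer, cache, dout) {
  B <- cache$d[4]
  P <- cache$ho * cache$wo
  dmat <- matrix(aperm(dout, c(1, 2, 4, 3)), nrow = P * B)
  dW <- crossprod(cache$col, dmat)
  db <- colSums(dmat)
  dcol <- tcrossprod(dmat, layer$W)
  dp <- cache$dp
  dxp <- numeric(dp[1] * dp[2] * dp[3] * B)
  agg <- rowsum(as.vector(dcol), group = as.vector(cache$big_idx))
  dxp[as.integer(rownames(agg))] <- agg
  dxp <- array(dxp, dim = c(dp[1], dp[2], dp[3], B))
  pad <- layer$pad
  dx <- if (pad > 0) {
    dxp[pad + seq_len(cache$d[1]), pad + seq_len(cache$d[2]), , , drop = FALSE]
  } else dxp
  list(dx = dx, grads = list(W = dW, b = db))
}

maxpool_forward <- function(x) {
  d <- dim(x)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  s1 <- x[seq_len(h2) * 2L - 1L, seq_len(w2) * 2L - 1L, , , drop = FALSE]
  s2 <- x[seq_len(h2) * 2L,      seq_len(w2) * 2L - 1L, , , drop = FALSE]
  s3 <- x[seq_len(h2) * 2L - 1L, seq_len(w2) * 2L, , , drop = FALSE]
  s4 <- x[seq_len(h2) * 2L,      seq_len(w2) * 2L, , , drop = FALSE]
  out <- pmax(s1, s2, s3, s4)
  which_max <- 1L * (s1 == out)
  which_max[s2 == out & which_max == 0] <- 2L
  which_max[s3 == out & which_max == 0] <- 3L
  which_max[s4 == out & which_max == 0] <- 4L
  list(out = out, cache = list(which = which_max, d = d))
}

maxpool_backward <- function(cache, dout) {
  d <- cache$d
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  dx <- array(0, dim = d)
  sel <- cache$which
  dx[seq_len(h2) * 2L - 1L, seq_len(w2) * 2L - 1L, , ] <- dout * (sel == 1L)
  dx[seq_len(h2) * 2L,      seq_len(w2) * 2L - 1L, , ] <-
    dx[seq_len(h2) * 2L, seq_len(w2) * 2L - 1L, , ] + dout * (sel == 2L)
  dx[seq_len(h2) * 2L - 1L, seq_len(w2) * 2L, , ] <-
    dx[seq_len(h2) * 2L - 1L, seq_len(w2) * 2L, , ] + dout * (sel == 3L)
  dx[seq_len(h2) * 2L,      seq_len(w2) * 2L, , ] <-
    dx[seq_len(h2) * 2L, seq_len(w2) * 2L, , ] + dout * (sel == 4L)
  dx
}

## ---- generic layer forward / backward --------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$type,
    linear = list(out = sweep(x %*% layer$W, 2, layer$b, "+"),
                  cache = list(x = x)),
    batchnorm = {
      if (training) {
        mu <- colMeans(x)
        va <- colMeans(sweep(x, 2, mu)^2)
        xc <- sweep(x, 2, mu)
        inv <- 1 / sqrt(va + layer$eps)
        xhat <- sweep(xc, 2, inv, "*")
        out <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
        list(out = out,
             cache = list(xhat = xhat, inv = inv, batch_mu = mu,
                          batch_var = va))
      } else {
        inv <- 1 / sqrt(layer$run_var + layer$eps)
        xhat <- sweep(sweep(x, 2, layer$run_mean), 2, inv, "*")
        out <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
        list(out = out, cache = list(xhat = xhat, inv = inv))
      }
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    dropout = {
      if (training && layer$p > 0) {
        mask <- (matrix(stats::runif(length(x)), nrow(x)) >= layer$p) /
          (1 - layer$p)
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    conv = conv_forward(layer, x),
    maxpool = maxpool_forward(x),
    gap = {
      d <- dim(x)
      m <- matrix(x, nrow = d[1] * d[2])  # (H*W) x (C*B)
      out <- matrix(colMeans(m), nrow = d[3])  # C x B
      list(out = t(out), cache = list(d = d))
    }
  )
}

layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    linear = list(dx = tcrossprod(dout, layer$W),
                  grads = list(W = crossprod(cache$x, dout),
                               b = colSums(dout))),
    batchnorm = {
      n <- nrow(dout)
      dgamma <- colSums(dout * cache$xhat)
      dbeta <- colSums(dout)
      dxhat <- sweep(dout, 2, layer$gamma, "*")
      if (!is.null(cache$batch_mu)) {
        dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dout),
                                   byrow = TRUE) -
                    sweep(cache$xhat, 2,
                          colMeans(dxhat * cache$xhat), "*"),
                    2, cache$inv, "*")
      } else {
        dx <- sweep(dxhat, 2, cache$inv, "*")
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    dropout = {
      dx <- if (is.null(cache$mask)) dout else dout * cache$mask
      list(dx = dx, grads = NULL)
    },
    conv = conv_backward(layer, cache, dout),
    maxpool = list(dx = maxpool_backward(cache, dout), grads = NULL),
    gap = {
      d <- cache$d
      per <- 1 / (d[1] * d[2])
      dx <- array(0, dim = d)
      for (b in seq_len(d[4])) {
        dx[, , , b] <- rep(dout[b, ] * per, each = d[1] * d[2])
      }
      list(dx = dx, grads = NULL)
    }
  )
}

# Forward through a layer list; returns final output plus per-layer caches.
seq_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    caches[[i]] <- r$cache
    x <- r$out
  }
  list(out = x, caches = caches)
}

# Backward through a layer list (optionally stopping early); returns the
# input gradient and per-layer parameter gradients.
seq_backward <- function(layers, caches, dout, stop_after = 0L) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (i <= stop_after) break
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    grads[i] <- list(r$grads)  # keep NULL placeholders for param-free layers
    dout <- r$dx
  }
  list(dx = dout, grads = grads)
}

# Update running batch-norm statistics after a training forward pass.
update_bn_stats <- function(layers, caches) {
  for (i in seq_along(layers)) {
    if (layers[[i]]$type == "batchnorm" && !is.null(caches[[i]]$batch_mu)) {
      m <- layers[[i]]$momentum
      layers[[i]]$run_mean <- (1 - m) * layers[[i]]$run_mean +
        m * caches[[i]]$batch_mu
      layers[[i]]$run_var <- (1 - m) * layers[[i]]$run_var +
        m * caches[[i]]$batch_var
    }
  }
  layers
}

## ---- Adam ------------------------------------------------------------

param_names <- function(layer) {
  switch(layer$type,
    linear = c("W", "b"),
    conv = c("W", "b"),
    batchnorm = c("gamma", "beta"),
    character(0))
}

adam_init <- function(layer_groups) {
  lapply(layer_groups, function(layers) {
    lapply(layers, function(layer) {
      pn <- param_names(layer)
      st <- lapply(pn, function(p) {
        list(m = layer[[p]] * 0, v = layer[[p]] * 0)
      })
      names(st) <- pn
      st
    })
  })
}

adam_update <- function(layers, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g[[p]]
      st$v <- beta2 * st$v + (1 - beta2) * g[[p]]^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

# Softmax cross-entropy loss and logits gradient; y integer 0-based.
softmax_xent <- function(logits, y) {
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  p <- e / rowSums(e)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, prob = p)
}
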