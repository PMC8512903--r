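# Recurrent cell implementations (vanilla RNN, LSTM, GRU) over a whole
# sequence, one direction at a time. Inputs are lists of length T of
# (batch x input) matrices; hidden states are (batch x M). Each forward
# caches what its backward needs; backward returns parameter gradients plus
# gradients w.r.t. the inputs (for stacking layers).
#
# Layer normalization, when enabled, is applied to the pre-activation of
# each gate (one normalization block per gate, with learned gain/bias).

n_gates <- function(cell) switch(cell, rnn = 1L, lstm = 4L, gru = 3L)

# parameter initialization: uniform(-1/sqrt(M), 1/sqrt(M)), the standard
# fan-in scheme for recurrent layers; LN gains start at 1, biases at 0
init_cell_params <- function(cell, input_size, M, layer_norm) {
  k <- 1 / sqrt(M)
  ru <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  g <- n_gates(cell)
  p <- if (cell == "gru") {
    list(
      Wx = ru(input_size, 3L * M),
      Whrz = ru(M, 2L * M),
      Whn = ru(M, M),
      b = stats::runif(3L * M, -k, k)
    )
  } else {
    list(
      Wx = ru(input_size, g * M),
      Wh = ru(M, g * M),
      b = stats::runif(g * M, -k, k)
    )
  }
  if (layer_norm) {
    p$gamma <- rep(1, g * M)
    p$beta <- rep(0, g * M)
  }
  p
}

# ---- vanilla RNN ---------------------------------------------------------

rnn_seq_forward <- function(X, p, layer_norm) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  M <- ncol(p$Wx)
  h_prev <- matrix(0, B, M)
  H <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (tau in seq_len(Tn)) {
    z <- add_rowvec(X[[tau]] %*% p$Wx + h_prev %*% p$Wh, p$b)
    ln <- NULL
    if (layer_norm) {
      ln <- ln_forward(z, p$gamma, p$beta)
      z <- ln$out
    }
    h <- tanh(z)
    cache[[tau]] <- list(h_prev = h_prev, ln = ln, h = h)
    H[[tau]] <- h
    h_prev <- h
  }
  list(h = H, cache = cache)
}

rnn_seq_backward <- function(dH, X, p, cache, layer_norm) {
  Tn <- length(X)
  g <- list(Wx = p$Wx * 0, Wh = p$Wh * 0, b = p$b * 0)
  if (layer_norm) {
    g$gamma <- p$gamma * 0
    g$beta <- p$beta * 0
  }
  tWx <- t(p$Wx)
  tWh <- t(p$Wh)
  dX <- vector("list", Tn)
  dh_next <- matrix(0, nrow(dH[[1]]), ncol(dH[[1]]))
  for (tau in rev(seq_len(Tn))) {
    cc <- cache[[tau]]
    dh <- dH[[tau]] + dh_next
    dz <- dh * (1 - cc$h * cc$h)
    if (layer_norm) {
      lb <- ln_backward(dz, cc$ln, p$gamma)
      g$gamma <- g$gamma + lb$dgamma
      g$beta <- g$beta + lb$dbeta
      dz <- lb$dz
    }
    g$b <- g$b + .colSums(dz, nrow(dz), ncol(dz))
    g$Wx <- g$Wx + crossprod(X[[tau]], dz)
    g$Wh <- g$Wh + crossprod(cc$h_prev, dz)
    dX[[tau]] <- dz %*% tWx
    dh_next <- dz %*% tWh
  }
  list(grads = g, dX = dX)
}

# ---- LSTM ----------------------------------------------------------------
# gate order in the 4M-wide blocks: input, forget, cell candidate, output

lstm_seq_forward_ref <- function(X, p, layer_norm) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  M <- ncol(p$Wx) %/% 4L
  i1 <- seq_len(M); i2 <- M + i1; i3 <- 2L * M + i1; i4 <- 3L * M + i1
  h_prev <- matrix(0, B, M)
  c_prev <- matrix(0, B, M)
  H <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (tau in seq_len(Tn)) {
    pre <- add_rowvec(X[[tau]] %*% p$Wx + h_prev %*% p$Wh, p$b)
    ln <- NULL
    if (layer_norm) {
      ln <- ln_forward_chunks(pre, p$gamma, p$beta, 4L)
      pre <- ln$out
    }
    gi <- sigmoid(pre[, i1, drop = FALSE])
    gf <- sigmoid(pre[, i2, drop = FALSE])
    gg <- tanh(pre[, i3, drop = FALSE])
    go <- sigmoid(pre[, i4, drop = FALSE])
    cst <- gf * c_prev + gi * gg
    tc <- tanh(cst)
    h <- go * tc
    cache[[tau]] <- list(h_prev = h_prev, c_prev = c_prev, ln = ln,
                         gi = gi, gf = gf, gg = gg, go = go, tc = tc)
    H[[tau]] <- h
    h_prev <- h
    c_prev <- cst
  }
  list(h = H, cache = cache)
}

lstm_seq_backward_ref <- function(dH, X, p, cache, layer_norm) {
  Tn <- length(X)
  B <- nrow(dH[[1]])
  M <- ncol(p$Wx) %/% 4L
  g <- list(Wx = p$Wx * 0, Wh = p$Wh * 0, b = p$b * 0)
  if (layer_norm) {
    g$gamma <- p$gamma * 0
    g$beta <- p$beta * 0
  }
  tWx <- t(p$Wx)
  tWh <- t(p$Wh)
  dX <- vector("list", Tn)
  dh_next <- matrix(0, B, M)
  dc_next <- matrix(0, B, M)
  for (tau in rev(seq_len(Tn))) {
    cc <- cache[[tau]]
    dh <- dH[[tau]] + dh_next
    dgo <- dh * cc$tc
    dc <- dc_next + dh * cc$go * (1 - cc$tc * cc$tc)
    dgf <- dc * cc$c_prev
    dgi <- dc * cc$gg
    dgg <- dc * cc$gi
    dc_next <- dc * cc$gf
    dq <- cbind(
      dgi * cc$gi * (1 - cc$gi),
      dgf * cc$gf * (1 - cc$gf),
      dgg * (1 - cc$gg * cc$gg),
      dgo * cc$go * (1 - cc$go)
    )
    if (layer_norm) {
      lb <- ln_backward_chunks(dq, cc$ln$caches, p$gamma, 4L)
      g$gamma <- g$gamma + lb$dgamma
      g$beta <- g$beta + lb$dbeta
      dq <- lb$dz
    }
    g$b <- g$b + .colSums(dq, nrow(dq), ncol(dq))
    g$Wx <- g$Wx + crossprod(X[[tau]], dq)
    g$Wh <- g$Wh + crossprod(cc$h_prev, dq)
    dX[[tau]] <- dq %*% tWx
    dh_next <- dq %*% tWh
  }
  list(grads = g, dX = dX)
}

# Fast path: the LSTM sequence kernel is compiled (RcppArmadillo), with the
# reference R implementation above kept for cross-checking in the tests.
# The kernel works on (B*T) x k matrices whose row block t is the batch at
# timestep t.

lstm_seq_forward <- function(X, p, layer_norm) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  M <- nrow(p$Wh)
  Xbig <- do.call(rbind, X)
  if (layer_norm) {
    gamma <- p$gamma
    beta <- p$beta
  } else {
    gamma <- beta <- numeric(4L * M)
  }
  res <- .lstm_seq_fwd_cpp(Xbig, B, Tn, p$Wx, p$Wh, p$b, gamma, beta,
                           layer_norm)
  H <- lapply(seq_len(Tn), function(t) {
    res$H[((t - 1L) * B + 1L):(t * B), , drop = FALSE]
  })
  list(h = H, cache = list(cpp = res, Xbig = Xbig))
}

lstm_seq_backward <- function(dH, X, p, cache, layer_norm, need_dx = TRUE) {
  Tn <- length(dH)
  B <- nrow(dH[[1]])
  M <- nrow(p$Wh)
  dHbig <- do.call(rbind, dH)
  cp <- cache$cpp
  gamma <- if (layer_norm) p$gamma else numeric(4L * M)
  res <- .lstm_seq_bwd_cpp(dHbig, cache$Xbig, B, Tn, p$Wx, p$Wh, gamma,
                           layer_norm, cp$GI, cp$GF, cp$GG, cp$GO, cp$TC,
                           cp$CPREV, cp$HPREV, cp$XHAT, cp$ISTD, need_dx)
  g <- list(Wx = res$Wx, Wh = res$Wh, b = as.numeric(res$b))
  if (layer_norm) {
    g$gamma <- as.numeric(res$gamma)
    g$beta <- as.numeric(res$beta)
  }
  dX <- NULL
  if (need_dx) {
    dX <- lapply(seq_len(Tn), function(t) {
      res$dX[((t - 1L) * B + 1L):(t * B), , drop = FALSE]
    })
  }
  list(grads = g, dX = dX)
}

# ---- GRU -----------------------------------------------------------------
# gate order: reset, update, candidate; the candidate path applies the reset
# gate to the recurrent term before (optional) normalization, as in the
# standard gated recurrent unit

gru_seq_forward <- function(X, p, layer_norm) {
  Tn <- length(X)
  B <- nrow(X[[1]])
  M <- ncol(p$Whn)
  i1 <- seq_len(M); i2 <- M + i1; i3 <- 2L * M + i1
  h_prev <- matrix(0, B, M)
  H <- vector("list", Tn)
  cache <- vector("list", Tn)
  for (tau in seq_len(Tn)) {
    px <- add_rowvec(X[[tau]] %*% p$Wx, p$b)
    hrz <- h_prev %*% p$Whrz
    aH <- h_prev %*% p$Whn
    pre_rz <- px[, c(i1, i2), drop = FALSE] + hrz
    ln_rz <- NULL
    if (layer_norm) {
      ln_rz <- ln_forward_chunks(pre_rz, p$gamma[c(i1, i2)],
                                 p$beta[c(i1, i2)], 2L)
      pre_rz <- ln_rz$out
    }
    gr <- sigmoid(pre_rz[, seq_len(M), drop = FALSE])
    gz <- sigmoid(pre_rz[, M + seq_len(M), drop = FALSE])
    pre_n <- px[, i3, drop = FALSE] + gr * aH
    ln_n <- NULL
    if (layer_norm) {
      ln_n <- ln_forward(pre_n, p$gamma[i3], p$beta[i3])
      pre_n <- ln_n$out
    }
    gn <- tanh(pre_n)
    h <- (1 - gz) * gn + gz * h_prev
    cache[[tau]] <- list(h_prev = h_prev, aH = aH, ln_rz = ln_rz, ln_n = ln_n,
                         gr = gr, gz = gz, gn = gn)
    H[[tau]] <- h
    h_prev <- h
  }
  list(h = H, cache = cache)
}

gru_seq_backward <- function(dH, X, p, cache, layer_norm) {
  Tn <- length(X)
  B <- nrow(dH[[1]])
  M <- ncol(p$Whn)
  i1 <- seq_len(M); i2 <- M + i1; i3 <- 2L * M + i1
  g <- list(Wx = p$Wx * 0, Whrz = p$Whrz * 0, Whn = p$Whn * 0, b = p$b * 0)
  if (layer_norm) {
    g$gamma <- p$gamma * 0
    g$beta <- p$beta * 0
  }
  tWx <- t(p$Wx)
  tWhrz <- t(p$Whrz)
  tWhn <- t(p$Whn)
  dX <- vector("list", Tn)
  dh_next <- matrix(0, B, M)
  for (tau in rev(seq_len(Tn))) {
    cc <- cache[[tau]]
    dh <- dH[[tau]] + dh_next
    dgz <- dh * (cc$h_prev - cc$gn)
    dgn <- dh * (1 - cc$gz)
    dh_prev <- dh * cc$gz
    dq_n <- dgn * (1 - cc$gn * cc$gn)
    if (layer_norm) {
      lb <- ln_backward(dq_n, cc$ln_n, p$gamma[i3])
      g$gamma[i3] <- g$gamma[i3] + lb$dgamma
      g$beta[i3] <- g$beta[i3] + lb$dbeta
      dq_n <- lb$dz
    }
    dgr <- dq_n * cc$aH
    daH <- dq_n * cc$gr
    g$Whn <- g$Whn + crossprod(cc$h_prev, daH)
    dh_prev <- dh_prev + daH %*% tWhn
    dq_rz <- cbind(dgr * cc$gr * (1 - cc$gr), dgz * cc$gz * (1 - cc$gz))
    if (layer_norm) {
      lb <- ln_backward_chunks(dq_rz, cc$ln_rz$caches, p$gamma[c(i1, i2)], 2L)
      g$gamma[c(i1, i2)] <- g$gamma[c(i1, i2)] + lb$dgamma
      g$beta[c(i1, i2)] <- g$beta[c(i1, i2)] + lb$dbeta
      dq_rz <- lb$dz
    }
    g$Whrz <- g$Whrz + crossprod(cc$h_prev, dq_rz)
    dh_prev <- dh_prev + dq_rz %*% tWhrz
    dpx <- cbind(dq_rz, dq_n)
    g$b <- g$b + .colSums(dpx, nrow(dpx), ncol(dpx))
    g$Wx <- g$Wx + crossprod(X[[tau]], dpx)
    dX[[tau]] <- dpx %*% tWx
    dh_next <- dh_prev
  }
  list(grads = g, dX = dX)
}

cell_seq_forward <- function(cell, X, p, layer_norm) {
  switch(cell,
    rnn = rnn_seq_forward(X, p, layer_norm),
    lstm = lstm_seq_forward(X, p, layer_norm),
    gru = gru_seq_forward(X, p, layer_norm)
  )
}

cell_seq_backward <- function(cell, dH, X, p, cache, layer_norm,
                              need_dx = TRUE) {
  switch(cell,
    rnn = rnn_seq_backward(dH, X, p, cache, layer_norm),
    lstm = lstm_seq_backward(dH, X, p, cache, layer_norm, need_dx),
    gru = gru_seq_backward(dH, X, p, cache, layer_norm)
  )
}
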