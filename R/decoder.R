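#' Configuration of an RNN-based neural decoder
#'
#' Defaults follow the reference settings of the three decoder families:
#' two bidirectional, layer-normalized recurrent layers; hidden size 128
#' (vanilla RNN), 256 (LSTM) or 128 (GRU); mini-batch 32/256/64; Adam with
#' learning rate 1e-4 and moment coefficients 0.9/0.999.
#'
#' @param cell `"rnn"`, `"lstm"` or `"gru"`.
#' @param n_layers Number of stacked recurrent layers (default 2).
#' @param hidden_size Hidden state width M per direction. `NULL` picks the
#'   cell's reference default (128/256/128).
#' @param bidirectional Process the window in both directions and
#'   concatenate the per-timestep states (default `TRUE`); the decoder's
#'   state width is then `H = 2M`.
#' @param batch_size Mini-batch size. `NULL` picks the cell default
#'   (32/256/64).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param adam_betas Length-2 numeric, Adam moment coefficients
#'   (default `c(0.9, 0.999)`).
#' @param epochs Training epochs (default 50).
#' @param seed Integer seed controlling initialization and batch shuffling.
#' @param layer_norm Apply layer normalization to the gate pre-activations
#'   inside every recurrent layer (default `TRUE`).
#' @param attention_size Width A of the attention module's hidden map.
#'   `NULL` (default) uses A = H, i.e. no bottleneck.
#' @param head_bias Include a bias in the fully connected prediction head
#'   (default `TRUE`; the head as written in the model definition is
#'   bias-free, set `FALSE` for that form).
#' @param val_fraction Fraction of training samples held out (seeded, random)
#'   as a validation set; when positive, the epoch with the lowest validation
#'   loss supplies the final weights. Default 0 (keep the last epoch).
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(cell = c("lstm", "rnn", "gru"), n_layers = 2L,
                           hidden_size = NULL, bidirectional = TRUE,
                           batch_size = NULL, learning_rate = 1e-4,
                           adam_betas = c(0.9, 0.999), epochs = 50L,
                           seed = 1L, layer_norm = TRUE,
                           attention_size = NULL, head_bias = TRUE,
                           val_fraction = 0) {
  cell <- match.arg(cell)
  if (is.null(hidden_size)) {
    hidden_size <- switch(cell, rnn = 128L, lstm = 256L, gru = 128L)
  }
  if (is.null(batch_size)) {
    batch_size <- switch(cell, rnn = 32L, lstm = 256L, gru = 64L)
  }
  if (hidden_size < 1L) stop("`hidden_size` must be >= 1", call. = FALSE)
  if (n_layers < 1L) stop("`n_layers` must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  if (epochs < 1L) stop("`epochs` must be >= 1", call. = FALSE)
  if (val_fraction < 0 || val_fraction >= 1) {
    stop("`val_fraction` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(cell = cell, n_layers = as.integer(n_layers),
         hidden_size = as.integer(hidden_size),
         bidirectional = isTRUE(bidirectional),
         batch_size = as.integer(batch_size),
         learning_rate = learning_rate, adam_betas = adam_betas,
         epochs = as.integer(epochs), seed = as.integer(seed),
         layer_norm = isTRUE(layer_norm),
         attention_size = if (is.null(attention_size)) NULL
                          else as.integer(attention_size),
         head_bias = isTRUE(head_bias), val_fraction = val_fraction),
    class = "decoder_config"
  )
}

state_width <- function(config) {
  config$hidden_size * (if (config$bidirectional) 2L else 1L)
}

#' Initialize decoder parameters
#'
#' Draws all weights from the uniform fan-in scheme under the current RNG
#' state. Exposed mainly for low-level use and tests; [train_decoder()]
#' seeds the RNG and calls this internally.
#'
#' @param config A [decoder_config()].
#' @param input_size Number of input features C per timestep.
#' @param output_size Number of kinematic output dimensions D.
#' @param use_tam Include temporal attention module parameters.
#' @return Nested parameter list with elements `layers` (per layer, per
#'   direction), optionally `tam` (`W` A-by-H, `b`, `v`) and `head`
#'   (`d` H-by-D, `c`).
#' @export
init_decoder_params <- function(config, input_size, output_size,
                                use_tam = TRUE) {
  M <- config$hidden_size
  H <- state_width(config)
  dirs <- if (config$bidirectional) 2L else 1L
  layers <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    isz <- if (l == 1L) input_size else H
    layers[[l]] <- lapply(seq_len(dirs), function(d) {
      init_cell_params(config$cell, isz, M, config$layer_norm)
    })
  }
  A <- if (is.null(config$attention_size)) H else config$attention_size
  p <- list(layers = layers)
  kh <- 1 / sqrt(H)
  if (use_tam) {
    ka <- 1 / sqrt(A)
    p$tam <- list(
      W = matrix(stats::runif(A * H, -kh, kh), A, H),
      b = numeric(A),
      v = stats::runif(A, -ka, ka)
    )
  }
  p$head <- list(
    d = matrix(stats::runif(H * output_size, -kh, kh), H, output_size),
    c = if (config$head_bias) stats::runif(output_size, -kh, kh)
        else numeric(output_size)
  )
  p
}

# ---- stacked bidirectional forward / backward ----------------------------

decoder_forward <- function(X, params, config) {
  dirs <- if (config$bidirectional) 2L else 1L
  Tn <- length(X)
  inp <- X
  layer_caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    dir_res <- vector("list", dirs)
    for (d in seq_len(dirs)) {
      Xd <- if (d == 2L) rev(inp) else inp
      r <- cell_seq_forward(config$cell, Xd, params$layers[[l]][[d]],
                            config$layer_norm)
      dir_res[[d]] <- list(Xd = Xd, res = r)
    }
    h1 <- dir_res[[1]]$res$h
    out <- if (dirs == 2L) {
      h2 <- rev(dir_res[[2]]$res$h)
      lapply(seq_len(Tn), function(tau) cbind(h1[[tau]], h2[[tau]]))
    } else {
      h1
    }
    layer_caches[[l]] <- dir_res
    inp <- out
  }
  list(H = inp, layer_caches = layer_caches)
}

decoder_backward <- function(dH, fwd, params, config) {
  dirs <- if (config$bidirectional) 2L else 1L
  Tn <- length(dH)
  M <- config$hidden_size
  glayers <- vector("list", config$n_layers)
  d_out <- dH
  for (l in rev(seq_len(config$n_layers))) {
    gdirs <- vector("list", dirs)
    d_in <- NULL
    for (d in seq_len(dirs)) {
      cols <- if (dirs == 2L && d == 2L) (M + 1L):(2L * M) else seq_len(M)
      dHd <- lapply(d_out, function(m) m[, cols, drop = FALSE])
      if (d == 2L) dHd <- rev(dHd)
      dc <- fwd$layer_caches[[l]][[d]]
      bk <- cell_seq_backward(config$cell, dHd, dc$Xd,
                              params$layers[[l]][[d]], dc$res$cache,
                              config$layer_norm, need_dx = l > 1L)
      gdirs[[d]] <- bk$grads
      if (l > 1L) {
        dX <- if (d == 2L) rev(bk$dX) else bk$dX
        d_in <- if (is.null(d_in)) dX
                else lapply(seq_len(Tn), function(tau) d_in[[tau]] + dX[[tau]])
      }
    }
    glayers[[l]] <- gdirs
    if (l > 1L) d_out <- d_in
  }
  glayers
}

# ---- temporal attention module + prediction heads ------------------------

tam_forward <- function(H, tam) {
  Tn <- length(H)
  B <- nrow(H[[1]])
  tW <- t(tam$W)
  U <- vector("list", Tn)
  logits <- matrix(0, B, Tn)
  for (tau in seq_len(Tn)) {
    u <- add_rowvec(H[[tau]] %*% tW, tam$b)
    u[u < 0] <- 0
    U[[tau]] <- u
    logits[, tau] <- u %*% tam$v
  }
  a <- softmax_rows(logits)
  hw <- matrix(0, B, ncol(H[[1]]))
  for (tau in seq_len(Tn)) hw <- hw + a[, tau] * H[[tau]]
  list(a = a, hw = hw, U = U)
}

head_forward <- function(hrep, head) {
  add_rowvec(hrep %*% head$d, head$c)
}

# Full batched forward: returns predictions and, with the TAM, the
# per-observation attention weights.
model_forward <- function(X, params, config, use_tam) {
  fwd <- decoder_forward(X, params, config)
  if (use_tam) {
    tf <- tam_forward(fwd$H, params$tam)
    yhat <- head_forward(tf$hw, params$head)
    list(yhat = yhat, a = tf$a, fwd = fwd, tf = tf)
  } else {
    yhat <- head_forward(fwd$H[[length(X)]], params$head)
    list(yhat = yhat, a = NULL, fwd = fwd, tf = NULL)
  }
}

# Mean-over-batch squared L2 loss and full analytic gradients.
model_loss_grads <- function(X, Y, params, config, use_tam) {
  Tn <- length(X)
  B <- nrow(Y)
  mf <- model_forward(X, params, config, use_tam)
  resid <- mf$yhat - Y
  loss <- mean(rowSums(resid * resid))
  dy <- 2 * resid / B
  H <- mf$fwd$H
  Hdim <- ncol(H[[1]])
  grads <- list()
  if (use_tam) {
    tf <- mf$tf
    ghead <- list(d = crossprod(tf$hw, dy), c = colSums(dy))
    if (!config$head_bias) ghead$c <- ghead$c * 0
    dhw <- dy %*% t(params$head$d)
    da <- matrix(0, B, Tn)
    dH <- vector("list", Tn)
    for (tau in seq_len(Tn)) {
      da[, tau] <- rowSums(dhw * H[[tau]])
      dH[[tau]] <- tf$a[, tau] * dhw
    }
    dlog <- tf$a * (da - rowSums(da * tf$a))
    gW <- params$tam$W * 0
    gb <- params$tam$b * 0
    gv <- params$tam$v * 0
    for (tau in seq_len(Tn)) {
      gv <- gv + as.numeric(crossprod(mf$tf$U[[tau]], dlog[, tau]))
      dU <- dlog[, tau] %o% params$tam$v
      dU[mf$tf$U[[tau]] <= 0] <- 0
      gb <- gb + colSums(dU)
      gW <- gW + crossprod(dU, H[[tau]])
      dH[[tau]] <- dH[[tau]] + dU %*% params$tam$W
    }
    grads$tam <- list(W = gW, b = gb, v = gv)
    grads$head <- ghead
  } else {
    grads$head <- list(d = crossprod(H[[Tn]], dy), c = colSums(dy))
    if (!config$head_bias) grads$head$c <- grads$head$c * 0
    zero <- matrix(0, B, Hdim)
    dH <- rep(list(zero), Tn)
    dH[[Tn]] <- dy %*% t(params$head$d)
  }
  glayers <- decoder_backward(dH, mf$fwd, params, config)
  out <- list(layers = glayers)
  if (use_tam) out$tam <- grads$tam
  out$head <- grads$head
  list(loss = loss, grads = out, yhat = mf$yhat, a = mf$a)
}

# ---- single-window operation surface -------------------------------------

window_to_batch <- function(window) {
  window <- as.matrix(window)
  lapply(seq_len(nrow(window)), function(tau) window[tau, , drop = FALSE])
}

check_window <- function(window, decoder) {
  if (!all(is.finite(window))) {
    stop("input window contains non-finite values", call. = FALSE)
  }
  if (ncol(as.matrix(window)) != decoder$input_size) {
    stop("window has the wrong number of units", call. = FALSE)
  }
}

#' Encode one input window into per-timestep hidden states
#'
#' Runs the recurrent encoder over a single window `x = {x_1, ..., x_T}`
#' (`tau = 1` oldest, `tau = T` most recent). With a bidirectional decoder
#' the forward and backward states are concatenated per timestep, `h_tau =
#' [h_fwd_tau, h_bwd_tau]`, giving width `H = 2M`.
#'
#' @param decoder A [trained_decoder] (from [train_decoder()]) or any list
#'   with elements `params`, `config`, `input_size`.
#' @param window Numeric matrix `T x C`.
#' @return Numeric matrix `T x H` of hidden states, one row per timestep.
#' @export
encode <- function(decoder, window) {
  check_window(window, decoder)
  fwd <- decoder_forward(window_to_batch(window), decoder$params,
                         decoder$config)
  do.call(rbind, fwd$H)
}

#' Attention weights of a hidden-state sequence
#'
#' Scores every timestep of an encoded window with the temporal attention
#' module: `u_tau = ReLU(W h_tau + b)`, followed by a softmax over
#' `u_tau' v`. The weights lie in `[0, 1]` and sum to one; identical hidden
#' states (or an all-zero map, since `ReLU(0) = 0`) give the uniform vector
#' `1/T`.
#'
#' @param h Numeric matrix `T x H` of hidden states (from [encode()]).
#' @param tam Attention parameters: list with `W` (`A x H`), `b` (length A),
#'   `v` (length A) -- e.g. `decoder$params$tam`.
#' @return Numeric vector of length T of attention weights.
#' @export
attention_weights <- function(h, tam) {
  h <- as.matrix(h)
  if (ncol(h) != ncol(tam$W)) {
    stop("hidden width does not match the attention parameters", call. = FALSE)
  }
  u <- add_rowvec(h %*% t(tam$W), tam$b)
  u[u < 0] <- 0
  logits <- as.numeric(u %*% tam$v)
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Attention-weighted aggregation of hidden states
#'
#' Forms the context vector `h_w = sum_tau a_tau h_tau`.
#'
#' @param h Numeric matrix `T x H`.
#' @param a Numeric vector of length T of attention weights.
#' @return Numeric vector of length H.
#' @export
aggregate_states <- function(h, a) {
  h <- as.matrix(h)
  if (length(a) != nrow(h)) {
    stop("attention vector length must equal the number of timesteps",
         call. = FALSE)
  }
  as.numeric(crossprod(h, a))
}

#' Predict a kinematic state with the attention head
#'
#' Composition encode -> attention -> aggregate -> fully connected head:
#' `yhat = d' h_w (+ c)`.
#'
#' @inheritParams encode
#' @return Numeric vector of length D.
#' @export
predict_with_tam <- function(decoder, window) {
  if (is.null(decoder$params$tam)) {
    stop("this decoder was trained without the attention module", call. = FALSE)
  }
  h <- encode(decoder, window)
  a <- attention_weights(h, decoder$params$tam)
  hw <- aggregate_states(h, a)
  as.numeric(head_forward(matrix(hw, 1L), decoder$params$head))
}

#' Predict a kinematic state from the final timestep only
#'
#' The retrained compact decoder aggregates nothing: `yhat = d' h_T (+ c)`
#' where `h_T` is the per-timestep state at the most recent timestep (for a
#' bidirectional decoder, the concatenation of the forward state after the
#' whole window and the backward state at position T). When the attention
#' mass is a point mass at `tau = T`, [predict_with_tam()] reduces exactly
#' to this head.
#'
#' @inheritParams encode
#' @return Numeric vector of length D.
#' @export
predict_final <- function(decoder, window) {
  h <- encode(decoder, window)
  hT <- h[nrow(h), , drop = FALSE]
  as.numeric(head_forward(hT, decoder$params$head))
}
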