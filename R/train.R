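batch_slices <- function(x_array, idx) {
  Tn <- dim(x_array)[2]
  C <- dim(x_array)[3]
  lapply(seq_len(Tn), function(tau) {
    m <- x_array[idx, tau, , drop = FALSE]
    dim(m) <- c(length(idx), C)
    m
  })
}

eval_loss <- function(x_array, y, idx, params, config, use_tam) {
  X <- batch_slices(x_array, idx)
  mf <- model_forward(X, params, config, use_tam)
  resid <- mf$yhat - y[idx, , drop = FALSE]
  mean(rowSums(resid * resid))
}

#' Train an RNN-based neural decoder
#'
#' Minimizes the squared L2 loss `sum_{y in B} (y - yhat)^2` over
#' mini-batches with Adam. With `use_tam = TRUE` the decoder carries the
#' temporal attention module and predicts through the attention-weighted
#' context vector; without it, prediction uses the hidden state at the final
#' timestep. Training is fully seeded (initialization and shuffling), so the
#' same dataset, configuration and seed reproduce the same model bit for bit
#' on one machine.
#'
#' After the last epoch the model is run once over the whole training set to
#' collect the per-observation attention weights (the raw material of
#' [select_T_star()]).
#'
#' @param dataset A `sequence_dataset` from [assemble_sequences()] (optionally
#'   normalized with [scale_dataset()]).
#' @param config A [decoder_config()].
#' @param use_tam Attach the temporal attention module (default `TRUE`).
#' @param verbose Print the loss every few epochs.
#' @return An object of class `trained_decoder`: list with `params`,
#'   `config`, `use_tam`, `T_len`, `input_size`, `output_size`, `losses`
#'   (per-epoch mean training loss), `val_losses` (if a validation fraction
#'   was set), `attention` (`n_samples x T` matrix, TAM only) and `norm`
#'   (normalization statistics, filled in by [run_tts()]).
#' @export
train_decoder <- function(dataset, config, use_tam = TRUE, verbose = FALSE) {
  stopifnot(inherits(dataset, "sequence_dataset"),
            inherits(config, "decoder_config"))
  n <- n_samples(dataset)
  if (n < 1L) stop("empty dataset", call. = FALSE)
  if (!all(is.finite(dataset$x)) || !all(is.finite(dataset$y))) {
    stop("dataset contains non-finite values", call. = FALSE)
  }
  set.seed(config$seed)
  C <- dim(dataset$x)[3]
  D <- ncol(dataset$y)

  val_idx <- integer(0)
  if (config$val_fraction > 0) {
    n_val <- max(1L, floor(config$val_fraction * n))
    val_idx <- sort(sample.int(n, n_val))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) < 1L) stop("no training samples left", call. = FALSE)

  params <- init_decoder_params(config, C, D, use_tam)
  skeleton <- params
  theta <- flatten_params(params)
  opt <- adam_init(length(theta))
  b1 <- config$adam_betas[1]
  b2 <- config$adam_betas[2]

  losses <- numeric(config$epochs)
  val_losses <- if (length(val_idx)) numeric(config$epochs) else NULL
  best_val <- Inf
  best_theta <- theta

  for (epoch in seq_len(config$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    starts <- seq(1L, length(ord), by = config$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      X <- batch_slices(dataset$x, idx)
      lg <- model_loss_grads(X, dataset$y[idx, , drop = FALSE],
                             params, config, use_tam)
      if (!is.finite(lg$loss)) {
        stop("training diverged: non-finite loss", call. = FALSE)
      }
      epoch_loss <- epoch_loss + lg$loss * length(idx)
      upd <- adam_step(theta, flatten_params(lg$grads), opt,
                       config$learning_rate, b1, b2)
      theta <- upd$theta
      opt <- upd$state
      params <- unflatten_params(theta, skeleton)
    }
    losses[epoch] <- epoch_loss / length(ord)
    if (length(val_idx)) {
      vl <- eval_loss(dataset$x, dataset$y, val_idx, params, config, use_tam)
      val_losses[epoch] <- vl
      if (vl < best_val) {
        best_val <- vl
        best_theta <- theta
      }
    }
    if (verbose && (epoch %% 5L == 0L || epoch == 1L)) {
      message(sprintf("epoch %3d  train loss %.5f%s", epoch, losses[epoch],
                      if (length(val_idx))
                        sprintf("  val loss %.5f", val_losses[epoch]) else ""))
    }
  }
  if (length(val_idx)) params <- unflatten_params(best_theta, skeleton)

  decoder <- structure(
    list(params = params, config = config, use_tam = use_tam,
         T_len = dataset$T_len, input_size = C, output_size = D,
         losses = losses, val_losses = val_losses,
         attention = NULL, norm = NULL),
    class = "trained_decoder"
  )
  if (use_tam) {
    decoder$attention <- collect_attention(decoder, dataset)
  }
  decoder
}

#' @export
print.trained_decoder <- function(x, ...) {
  cat(sprintf(
    "<trained_decoder> %s%s, %d layer(s), M=%d, T=%d, %s, final loss %.4g\n",
    x$config$cell, if (x$config$bidirectional) " (bidirectional)" else "",
    x$config$n_layers, x$config$hidden_size, x$T_len,
    if (x$use_tam) "with TAM" else "final-state head",
    x$losses[length(x$losses)]
  ))
  invisible(x)
}

#' Collect attention weights over a dataset
#'
#' Runs a trained attention decoder over every observation and stacks the
#' attention vectors into an `n_samples x T` matrix (rows sum to one).
#'
#' @param decoder A `trained_decoder` trained with `use_tam = TRUE`.
#' @param dataset A `sequence_dataset` with the decoder's window length.
#' @return Numeric matrix `n_samples x T`.
#' @export
collect_attention <- function(decoder, dataset) {
  if (!decoder$use_tam || is.null(decoder$params$tam)) {
    stop("decoder has no attention module", call. = FALSE)
  }
  n <- n_samples(dataset)
  Tn <- dataset$T_len
  out <- matrix(0, n, Tn)
  starts <- seq(1L, n, by = max(decoder$config$batch_size, 256L))
  for (s in starts) {
    idx <- s:min(s + max(decoder$config$batch_size, 256L) - 1L, n)
    X <- batch_slices(dataset$x, idx)
    mf <- model_forward(X, decoder$params, decoder$config, TRUE)
    out[idx, ] <- mf$a
  }
  out
}

#' Predict kinematics for a dataset
#'
#' @param object A `trained_decoder`.
#' @param dataset A `sequence_dataset` whose window length matches the
#'   decoder's training length.
#' @param ... Unused.
#' @return Numeric matrix `n_samples x D` of predictions.
#' @export
predict.trained_decoder <- function(object, dataset, ...) {
  stopifnot(inherits(dataset, "sequence_dataset"))
  if (dataset$T_len != object$T_len) {
    stop(sprintf("dataset window length (%d) differs from the decoder's (%d)",
                 dataset$T_len, object$T_len), call. = FALSE)
  }
  n <- n_samples(dataset)
  out <- matrix(0, n, object$output_size)
  bs <- max(object$config$batch_size, 256L)
  for (s in seq(1L, n, by = bs)) {
    idx <- s:min(s + bs - 1L, n)
    X <- batch_slices(dataset$x, idx)
    mf <- model_forward(X, object$params, object$config, object$use_tam)
    out[idx, ] <- mf$yhat
  }
  out
}

#' Normalize a sequence dataset with given per-unit statistics
#'
#' Z-scores the rate features of an assembled dataset using statistics
#' computed on the training split only (so retraining at a shorter window
#' reuses identical statistics). Units with zero spread are left unscaled.
#'
#' @param dataset A `sequence_dataset`.
#' @param center,scale Numeric vectors of length C (e.g. from
#'   [norm_stats()]).
#' @return The dataset with normalized `x`.
#' @export
scale_dataset <- function(dataset, center, scale) {
  stopifnot(inherits(dataset, "sequence_dataset"))
  C <- dim(dataset$x)[3]
  stopifnot(length(center) == C, length(scale) == C)
  scale[scale == 0] <- 1
  for (u in seq_len(C)) {
    dataset$x[, , u] <- (dataset$x[, , u] - center[u]) / scale[u]
  }
  dataset
}

#' Per-unit normalization statistics of a session
#'
#' @param session A [binned_session()] (normally the training split).
#' @return List with numeric vectors `center` (means) and `scale` (sds).
#' @export
norm_stats <- function(session) {
  stopifnot(inherits(session, "binned_session"))
  list(center = colMeans(session$rates),
       scale = apply(session$rates, 2L, stats::sd))
}
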