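#' Average attention weights over observations
#'
#' Elementwise mean of the per-observation attention vectors:
#' `abar_tau = (1/N) sum_t a_tau^t`.
#'
#' @param records Either a numeric matrix (`N x T`, one attention vector per
#'   row) or a list of equal-length numeric vectors.
#' @return Numeric vector of length T (sums to 1 when every record does).
#' @export
average_attention <- function(records) {
  if (is.list(records)) {
    if (length(records) == 0L) stop("no attention records", call. = FALSE)
    lens <- lengths(records)
    if (length(unique(lens)) != 1L) {
      stop("attention records have mixed lengths", call. = FALSE)
    }
    records <- do.call(rbind, records)
  }
  records <- as.matrix(records)
  if (nrow(records) < 1L) stop("no attention records", call. = FALSE)
  if (any(records < 0)) {
    stop("attention weights must be nonnegative", call. = FALSE)
  }
  colMeans(records)
}

#' Select the essential window length T*
#'
#' Computes, for every candidate length `k = 1..T`, the cumulative
#' percentage of averaged attention mass held by the `k` most recent
#' timesteps, `a*(k) = 100 * sum_{tau = T-k+1}^{T} abar_tau / sum_tau
#' abar_tau`, and selects the minimum `k` whose cumulative percentage
#' reaches the threshold. The comparison is inclusive (`>=`), which
#' guarantees existence (`k = T` gives 100%) and makes tie cases such as a
#' uniform `abar` with threshold 95 and `T = 20` select `T* = 19` rather
#' than 20. The statistic is a ratio, so any positive rescaling of `abar`
#' leaves the selection unchanged.
#'
#' @param avg_weights Numeric vector `abar` of averaged attention weights
#'   (nonnegative, positive sum; it need not be normalized).
#' @param threshold Percentage threshold in (0, 100] (default 95).
#' @return An object of class `selection_result`: list with `avg_weights`
#'   (normalized to sum 1), `cumulative_pct` (`a*(k)`, nondecreasing,
#'   ending at 100), `T_star`, `threshold`.
#' @export
select_T_star <- function(avg_weights, threshold = 95) {
  a <- as.numeric(avg_weights)
  if (length(a) < 1L || anyNA(a)) {
    stop("`avg_weights` must be a nonempty numeric vector", call. = FALSE)
  }
  if (any(a < 0)) stop("`avg_weights` must be nonnegative", call. = FALSE)
  tot <- sum(a)
  if (tot <= 0) {
    stop("`avg_weights` must have a positive sum (all-zero weights carry no salience)",
         call. = FALSE)
  }
  if (threshold <= 0 || threshold > 100) {
    stop("`threshold` must be a percentage in (0, 100]", call. = FALSE)
  }
  cum <- 100 * cumsum(rev(a)) / tot   # cum[k]: mass of the k most recent steps
  cum[length(a)] <- 100
  T_star <- which(cum >= threshold)[1]
  structure(
    list(avg_weights = a / tot, cumulative_pct = cum,
         T_star = as.integer(T_star), threshold = threshold),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> T*=%d of T=%d (>= %g%% of attention mass; a*(T*) = %.2f%%)\n",
    x$T_star, length(x$avg_weights), x$threshold, x$cumulative_pct[x$T_star]
  ))
  invisible(x)
}

#' Attention matrix and highlighted-timestep trace
#'
#' Stacks the per-observation attention vectors into an `observations x T`
#' matrix (row `t` is `a^t`) and extracts, per observation, the most
#' highlighted timestep (the row argmax, ties broken toward the most recent
#' timestep). Plotted against clock time, runs of the trace that decrease by
#' one bin per observation indicate that one and the same piece of neural
#' activity stays highlighted while it recedes into the window.
#'
#' @param records Numeric matrix `N x T` or list of attention vectors.
#' @return List with `matrix` (`N x T`) and `argmax` (integer vector of
#'   length N).
#' @export
attention_matrix <- function(records) {
  if (is.list(records)) records <- do.call(rbind, records)
  records <- as.matrix(records)
  am <- apply(records, 1L, function(r) max(which(r == max(r))))
  list(matrix = records, argmax = as.integer(am))
}

#' Run the full timestep-selection pipeline on one session
#'
#' The three-step, one-pass procedure: (1) train a decoder with the temporal
#' attention module on windows of length `T_len` over the training split;
#' (2) average its attention weights over the training observations and
#' select the minimal recent window `T*` covering at least `threshold`
#' percent of the attention mass; (3) retrain a fresh decoder without the
#' attention module (final-timestep head) on windows of length `T*`, and
#' report test metrics for both models on the held-out suffix of the
#' session.
#'
#' Rates are z-scored per unit with training-split statistics (default on).
#' The retrained decoder starts from a fresh seeded initialization and uses
#' the full epoch budget unless `retrain_epochs` shortens it.
#'
#' @param session A [binned_session()].
#' @param T_len Initial (long) window length T.
#' @param config A [decoder_config()].
#' @param split A [split_spec()] with the prefix policy.
#' @param threshold Attention-mass percentage for [select_T_star()]
#'   (default 95).
#' @param retrain_epochs Optional epoch budget for the retraining step.
#' @param normalize Z-score rates with training statistics (default `TRUE`).
#' @return An object of class `tts_report`: list with `selection`
#'   ([select_T_star()] result), `metrics_full` and `metrics_retrained`
#'   ([metric_report()]s on the same test split), `attention`
#'   (training-split attention matrix), the two trained decoders, the
#'   configurations and the normalization statistics.
#' @export
run_tts <- function(session, T_len, config, split, threshold = 95,
                    retrain_epochs = NULL, normalize = TRUE) {
  stopifnot(inherits(session, "binned_session"),
            inherits(config, "decoder_config"),
            inherits(split, "split_spec"))
  if (split$policy != "prefix") {
    stop("run_tts() uses the prefix split policy", call. = FALSE)
  }
  parts <- split_session(session, split)
  ns <- if (normalize) norm_stats(parts$train) else NULL
  prep <- function(sess, T_len) {
    ds <- assemble_sequences(sess, T_len)
    if (normalize) ds <- scale_dataset(ds, ns$center, ns$scale)
    ds
  }
  cfg_full <- config
  if (split$val_fraction > 0) cfg_full$val_fraction <- split$val_fraction

  ds_train <- prep(parts$train, T_len)
  ds_test <- prep(parts$test, T_len)
  full <- train_decoder(ds_train, cfg_full, use_tam = TRUE)
  full$norm <- ns

  sel <- select_T_star(average_attention(full$attention), threshold)

  cfg_re <- cfg_full
  cfg_re$seed <- split_seed(config$seed, 2L)[2]
  if (!is.null(retrain_epochs)) cfg_re$epochs <- as.integer(retrain_epochs)
  ds_train_s <- prep(parts$train, sel$T_star)
  ds_test_s <- prep(parts$test, sel$T_star)
  compact <- train_decoder(ds_train_s, cfg_re, use_tam = FALSE)
  compact$norm <- ns

  pred_full <- predict(full, ds_test)
  pred_compact <- predict(compact, ds_test_s)

  structure(
    list(
      selection = sel,
      metrics_full = metric_report(ds_test$y, pred_full),
      metrics_retrained = metric_report(ds_test_s$y, pred_compact),
      attention = full$attention,
      decoder_full = full,
      decoder_retrained = compact,
      T_len = as.integer(T_len),
      threshold = threshold,
      config = cfg_full,
      retrain_config = cfg_re,
      norm = ns
    ),
    class = "tts_report"
  )
}

#' @export
print.tts_report <- function(x, ...) {
  cat(sprintf("<tts_report> T=%d -> T*=%d (threshold %g%%)\n",
              x$T_len, x$selection$T_star, x$threshold))
  cat(sprintf("  full-T decoder:      test R2 = %.3f, CC = %.3f\n",
              x$metrics_full$r2_mean, x$metrics_full$cc_mean))
  cat(sprintf("  retrained T* decoder: test R2 = %.3f, CC = %.3f\n",
              x$metrics_retrained$r2_mean, x$metrics_retrained$cc_mean))
  invisible(x)
}
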