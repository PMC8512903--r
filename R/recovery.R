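#' Default decoder configuration for the synthetic recovery study
#'
#' The scaled-down LSTM used by [tts_recovery_study()]: one unidirectional
#' layer-normalized layer, hidden width 16, batch 64, learning rate 2e-3,
#' 100 epochs. The model is two orders of magnitude smaller than the
#' reference decoders, hence the larger learning rate. Two choices matter
#' for interpretability rather than raw accuracy: the encoder is
#' unidirectional, because under bidirectional processing every
#' concatenated state covers the entire window and attention loses its
#' positional meaning; and the hidden width is kept moderate, because an
#' oversized state lets the final timesteps summarize the whole informative
#' zone and decouples the attention profile from the information horizon.
#'
#' @param seed Integer seed.
#' @param epochs Training epochs (default 100).
#' @return A [decoder_config()].
#' @export
recovery_config <- function(seed = 1L, epochs = 100L) {
  decoder_config("lstm", n_layers = 1L, hidden_size = 16L,
                 bidirectional = FALSE, batch_size = 64L,
                 learning_rate = 2e-3, epochs = epochs, seed = seed)
}

#' Parameter-recovery study for the timestep selection
#'
#' Generates synthetic sessions with known information horizons `L`, runs
#' the full train/select/retrain pipeline ([run_tts()]) for several seeds
#' per `L`, and tabulates the selected `T*` together with the test
#' performance of the full-length and retrained decoders. This is the
#' package's central validation: on sessions where the essential timestep
#' count is known by construction, the seed-median `T*` should track `L`,
#' and the retrained compact decoder should match the full decoder's test
#' accuracy.
#'
#' @param L_values Injected lag windows to study (default `c(2, 4, 6)`).
#' @param seeds Seeds, one pipeline run per seed (default `1:5`).
#' @param n_bins Session length (default 3000).
#' @param n_units Units C (default 32).
#' @param T_len Initial window length (default 12).
#' @param train_end Prefix split point (default 2500).
#' @param threshold Attention-mass threshold (default 95).
#' @param config_fn Function `seed -> decoder_config` (default
#'   [recovery_config()]).
#' @param retrain_epochs Epoch budget for the retraining step. `NULL` (the
#'   default) retrains with the full epoch budget from a fresh
#'   initialization; a smaller value exposes the quick-recalibration
#'   variant.
#' @param verbose Print one line per run.
#' @return Data frame with one row per (L, seed): `L`, `seed`, `T_star`,
#'   `r2_full`, `r2_retrained`, `cc_full`, `cc_retrained`.
#' @export
tts_recovery_study <- function(L_values = c(2L, 4L, 6L), seeds = 1:5,
                               n_bins = 3000L, n_units = 32L, T_len = 12L,
                               train_end = 2500L, threshold = 95,
                               config_fn = recovery_config,
                               retrain_epochs = NULL, verbose = FALSE) {
  rows <- list()
  for (L in L_values) {
    for (seed in seeds) {
      sess <- make_session(synthetic_config(
        n_bins = n_bins, n_units = n_units, lag_window = L,
        seed = split_seed(seed * 131 + L, 1L)
      ))
      rep <- run_tts(sess, T_len = T_len, config = config_fn(seed),
                     split = split_spec(train_end = train_end),
                     threshold = threshold, retrain_epochs = retrain_epochs)
      rows[[length(rows) + 1L]] <- data.frame(
        L = L, seed = seed, T_star = rep$selection$T_star,
        r2_full = rep$metrics_full$r2_mean,
        r2_retrained = rep$metrics_retrained$r2_mean,
        cc_full = rep$metrics_full$cc_mean,
        cc_retrained = rep$metrics_retrained$cc_mean
      )
      if (verbose) {
        message(sprintf(
          "L=%d seed=%d: T*=%d, R2 full=%.3f retrained=%.3f",
          L, seed, rep$selection$T_star, rep$metrics_full$r2_mean,
          rep$metrics_retrained$r2_mean
        ))
      }
    }
  }
  do.call(rbind, rows)
}
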