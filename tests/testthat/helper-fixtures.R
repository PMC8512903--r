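# Small deterministic fixtures shared across tests.

tiny_session <- function(nb = 50L, C = 10L, D = 2L, seed = 123L) {
  set.seed(seed)
  binned_session(
    rates = matrix(runif(nb * C, 0, 20), nb, C),
    kinematics = matrix(rnorm(nb * D), nb, D),
    bin_width = 0.064,
    session_id = sprintf("tiny-%d", seed)
  )
}

tiny_config <- function(cell = "rnn", ..., seed = 7L) {
  decoder_config(cell = cell, n_layers = 1L, hidden_size = 4L,
                 batch_size = 8L, epochs = 2L, learning_rate = 1e-3,
                 seed = seed, ...)
}

# a quick trained decoder on a tiny dataset, for the operation surface
tiny_decoder <- function(use_tam = TRUE, cell = "rnn", T_len = 4L, ...) {
  ds <- assemble_sequences(tiny_session(), T_len)
  train_decoder(ds, tiny_config(cell = cell, ...), use_tam = use_tam)
}

# the scaled-down experiment configuration used by the recovery studies
recovery_decoder_config <- function(seed) {
  decoder_config("lstm", n_layers = 1L, hidden_size = 8L,
                 bidirectional = TRUE, batch_size = 64L,
                 learning_rate = 2e-3, epochs = 60L, seed = seed)
}
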