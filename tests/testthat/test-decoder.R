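# Reference single-step implementations used as oracles.
ref_layer_norm <- function(z, gamma, beta, eps = 1e-5) {
  mu <- mean(z)
  s2 <- mean((z - mu)^2)
  gamma * (z - mu) / sqrt(s2 + eps) + beta
}

test_that("zero input with zero parameters gives all-zero hidden states", {
  cfg <- tiny_config("rnn")
  p <- init_decoder_params(cfg, 3L, 2L, use_tam = TRUE)
  zero <- function(x) {
    if (is.numeric(x)) x * 0 else lapply(x, zero)
  }
  p$layers <- zero(p$layers)   # LN gains go to 0 too: still maps 0 to 0
  dec <- list(params = p, config = cfg, input_size = 3L)
  h <- encode(dec, matrix(0, 5, 3))
  expect_equal(h, matrix(0, 5, cfg$hidden_size * 2))
})

test_that("encode is pure and rejects non-finite windows", {
  dec <- tiny_decoder(cell = "gru")
  w <- matrix(runif(4 * 10), 4, 10)
  expect_identical(encode(dec, w), encode(dec, w))
  w[2, 3] <- NaN
  expect_error(encode(dec, w), "non-finite")
})

test_that("a single-timestep window equals one hand-rolled cell step", {
  cfg <- decoder_config("rnn", n_layers = 1L, hidden_size = 3L,
                        bidirectional = FALSE, seed = 21L)
  set.seed(21)
  p <- init_decoder_params(cfg, 2L, 2L, use_tam = FALSE)
  x <- c(0.3, -1.2)
  h <- encode(list(params = p, config = cfg, input_size = 2L),
              matrix(x, 1, 2))
  lp <- p$layers[[1]][[1]]
  pre <- as.numeric(x %*% lp$Wx) + lp$b      # h_0 = 0
  expect_equal(as.numeric(h),
               tanh(ref_layer_norm(pre, lp$gamma, lp$beta)),
               tolerance = 1e-12)
})

test_that("attention weights follow the ReLU/softmax construction", {
  Tn <- 4L
  H <- 6L
  set.seed(3)
  tam <- list(W = matrix(rnorm(H * H), H, H), b = rnorm(H), v = rnorm(H))

  # identical hidden states -> uniform weights
  h_same <- matrix(rep(rnorm(H), each = Tn), Tn, H)
  expect_equal(attention_weights(h_same, tam), rep(1 / Tn, Tn))

  # zero map -> ReLU(0) = 0 logits -> uniform regardless of states
  tam0 <- list(W = matrix(0, H, H), b = rep(0, H), v = rnorm(H))
  h_any <- matrix(rnorm(Tn * H), Tn, H)
  expect_equal(attention_weights(h_any, tam0), rep(1 / Tn, Tn))

  # small explicit instance against an independent scalar evaluation
  W <- matrix(c(0.5, -0.2, 0.1, 0.4, -0.3, 0.25), 3, 2)
  b <- c(0.05, -0.1, 0.2)
  v <- c(1.2, -0.7, 0.3)
  h <- matrix(c(0.3, -0.6, 1.1, 0.2, -0.4, 0.9), 3, 2)
  logits <- sapply(1:3, function(tau) {
    u <- pmax(W %*% h[tau, ] + b, 0)
    sum(u * v)
  })
  expected <- exp(logits) / sum(exp(logits))
  expect_equal(attention_weights(h, list(W = W, b = b, v = v)), expected,
               tolerance = 1e-8)
})

test_that("aggregation is the attention-weighted sum of hidden states", {
  set.seed(9)
  h <- matrix(rnorm(5 * 4), 5, 4)
  one_hot <- c(0, 0, 0, 0, 1)
  expect_equal(aggregate_states(h, one_hot), h[5, ])
  expect_equal(aggregate_states(h, rep(0.2, 5)), colMeans(h))
  a <- runif(5)
  a <- a / sum(a)
  loop <- numeric(4)
  for (tau in 1:5) loop <- loop + a[tau] * h[tau, ]
  expect_equal(aggregate_states(h, a), loop, tolerance = 1e-12)
  expect_error(aggregate_states(h, a[1:3]), "length")
})

test_that("the attention head reduces to the final-state head under a point mass", {
  for (cell in c("rnn", "lstm", "gru")) {
    dec <- tiny_decoder(use_tam = TRUE, cell = cell)
    set.seed(55)
    for (i in 1:5) {
      w <- matrix(runif(4 * 10, 0, 5), 4, 10)
      h <- encode(dec, w)
      hw <- aggregate_states(h, c(0, 0, 0, 1))   # point mass at tau = T
      y_tam <- as.numeric(hw %*% dec$params$head$d + dec$params$head$c)
      expect_equal(y_tam, predict_final(dec, w), tolerance = 1e-10)
    }
  }
})

test_that("predict_final is the head applied to the last hidden state", {
  dec <- tiny_decoder(use_tam = FALSE, cell = "lstm")
  w <- matrix(runif(40, 0, 3), 4, 10)
  h <- encode(dec, w)
  expect_equal(predict_final(dec, w),
               as.numeric(h[4, ] %*% dec$params$head$d + dec$params$head$c),
               tolerance = 1e-12)

  # T = 1: attention collapses, both heads coincide
  dec1 <- tiny_decoder(use_tam = TRUE, T_len = 1L)
  w1 <- matrix(runif(10, 0, 3), 1, 10)
  expect_equal(predict_with_tam(dec1, w1), predict_final(dec1, w1),
               tolerance = 1e-10)

  # zero head -> zero output
  dec$params$head$d[] <- 0
  dec$params$head$c[] <- 0
  expect_equal(predict_final(dec, w), c(0, 0))
})

test_that("analytic gradients match finite differences on tiny instances", {
  for (case in list(list(cell = "rnn", ln = TRUE, tam = TRUE),
                    list(cell = "lstm", ln = TRUE, tam = TRUE),
                    list(cell = "gru", ln = TRUE, tam = TRUE),
                    list(cell = "lstm", ln = FALSE, tam = FALSE))) {
    set.seed(42)
    cfg <- decoder_config(case$cell, n_layers = 2L, hidden_size = 2L,
                          bidirectional = TRUE, layer_norm = case$ln,
                          seed = 42L)
    Tn <- 3L; B <- 2L; C <- 2L; D <- 2L
    params <- init_decoder_params(cfg, C, D, case$tam)
    X <- lapply(1:Tn, function(t) matrix(rnorm(B * C), B, C))
    Y <- matrix(rnorm(B * D), B, D)
    lg <- ttsdecode:::model_loss_grads(X, Y, params, cfg, case$tam)
    ga <- ttsdecode:::flatten_params(lg$grads)
    theta <- ttsdecode:::flatten_params(params)
    eps <- 1e-5
    gn <- vapply(seq_along(theta), function(i) {
      tp <- theta; tp[i] <- tp[i] + eps
      tm <- theta; tm[i] <- tm[i] - eps
      (ttsdecode:::model_loss_grads(
         X, Y, ttsdecode:::unflatten_params(tp, params), cfg, case$tam)$loss -
       ttsdecode:::model_loss_grads(
         X, Y, ttsdecode:::unflatten_params(tm, params), cfg, case$tam)$loss) /
        (2 * eps)
    }, numeric(1))
    rel <- abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-6)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("training fits a constant-target dataset and is seed-reproducible", {
  set.seed(77)
  nb <- 60L
  sess <- binned_session(matrix(runif(nb * 6, 0, 10), nb, 6),
                         matrix(1.5, nb, 2))
  ds <- assemble_sequences(sess, 4L)
  cfg <- decoder_config("gru", n_layers = 1L, hidden_size = 4L,
                        batch_size = 16L, epochs = 40L,
                        learning_rate = 5e-3, seed = 5L)
  dec <- train_decoder(ds, cfg, use_tam = FALSE)
  pred <- predict(dec, ds)
  mse <- mean((pred - ds$y)^2)
  zero_mse <- mean(ds$y^2)             # variance of a zero predictor
  expect_lt(mse, zero_mse)

  dec2 <- train_decoder(ds, cfg, use_tam = FALSE)
  expect_identical(dec$losses, dec2$losses)
  expect_identical(dec$params, dec2$params)
  expect_error(train_decoder(ds, cfg, use_tam = TRUE), NA)
})

test_that("attention normalization holds for every observation after training", {
  dec <- tiny_decoder(use_tam = TRUE, cell = "lstm")
  expect_true(all(dec$attention >= 0))
  expect_equal(rowSums(dec$attention), rep(1, nrow(dec$attention)),
               tolerance = 1e-6)
})

test_that("decoders recover kinematics from a low-noise synthetic session", {
  sess <- make_session(synthetic_config(n_bins = 2000L, n_units = 32L,
                                        lag_window = 3L, noise_scale = 0.5,
                                        seed = 11L))
  sp <- split_session(sess, split_spec(train_end = 1600L))
  ns <- norm_stats(sp$train)
  tr <- scale_dataset(assemble_sequences(sp$train, 8L), ns$center, ns$scale)
  te <- scale_dataset(assemble_sequences(sp$test, 8L), ns$center, ns$scale)
  cfg <- decoder_config("lstm", n_layers = 1L, hidden_size = 16L,
                        batch_size = 64L, learning_rate = 2e-3,
                        epochs = 30L, seed = 1L)
  dec <- train_decoder(tr, cfg, use_tam = TRUE)
  r2 <- r_squared(te$y, predict(dec, te))
  expect_gt(r2, 0.8)
})
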