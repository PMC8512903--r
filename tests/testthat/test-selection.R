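# Independent oracle: exhaustive scan over all candidate window lengths.
brute_force_T_star <- function(a, threshold) {
  Tn <- length(a)
  for (k in seq_len(Tn)) {
    pct <- 100 * sum(a[(Tn - k + 1):Tn]) / sum(a)
    if (k == Tn) pct <- 100
    if (pct >= threshold) return(k)
  }
  Tn
}

test_that("average_attention is the elementwise mean over observations", {
  expect_equal(average_attention(list(c(0.2, 0.8), c(0.6, 0.4))), c(0.4, 0.6))
  one <- c(0.1, 0.2, 0.7)
  expect_equal(average_attention(list(one)), one)
  expect_equal(average_attention(do.call(rbind, rep(list(one), 13))), one)
  expect_error(average_attention(list(c(0.5, 0.5), c(1, 0, 0))), "mixed")
  expect_error(average_attention(list()), "no attention")
  expect_error(average_attention(matrix(c(-0.1, 1.1), 1)), "nonnegative")
})

test_that("select_T_star picks the minimal recent window reaching the threshold", {
  s <- select_T_star(c(0.05, 0.05, 0.90), 95)
  expect_equal(s$T_star, 2L)                      # last-2 mass is exactly 95%
  expect_equal(s$cumulative_pct, c(90, 95, 100))

  expect_equal(select_T_star(c(0, 0, 0, 0, 1), 100)$T_star, 1L)
  expect_equal(select_T_star(c(0, 0, 0, 0, 1), 5)$T_star, 1L)

  u <- rep(1 / 20, 20)
  expect_equal(select_T_star(u, 95)$T_star, 19L)  # 19/20 = 95%
  expect_equal(select_T_star(u, 95)$T_star, brute_force_T_star(u, 95))

  expect_error(select_T_star(rep(0, 5)), "positive sum")
  expect_error(select_T_star(c(0.2, -0.1)), "nonnegative")
  expect_error(select_T_star(c(0.5, 0.5), 101), "threshold")
})

test_that("selection matches the exhaustive oracle on random attention vectors", {
  set.seed(99)
  for (i in 1:300) {
    Tn <- sample(1:30, 1)
    a <- runif(Tn)^3
    if (sum(a) == 0) a[1] <- 1
    thr <- runif(1, 1, 100)
    expect_identical(select_T_star(a, thr)$T_star,
                     as.integer(brute_force_T_star(a, thr)))
  }
})

test_that("selection result invariants hold: nondecreasing cumulative mass, tight T*", {
  set.seed(4)
  for (i in 1:50) {
    a <- runif(sample(2:25, 1))
    s <- select_T_star(a, 95)
    expect_true(all(diff(s$cumulative_pct) >= -1e-12))
    expect_equal(s$cumulative_pct[length(a)], 100)
    expect_gte(s$cumulative_pct[s$T_star], 95)
    if (s$T_star > 1L) expect_lt(s$cumulative_pct[s$T_star - 1L], 95)
    expect_equal(sum(s$avg_weights), 1)
  }
})

test_that("T* is monotone in the threshold and invariant to rescaling", {
  set.seed(17)
  for (i in 1:300) {
    a <- runif(sample(2:30, 1))^2
    if (sum(a) == 0) a[1] <- 1
    t1 <- runif(1, 1, 99)
    t2 <- runif(1, t1, 100)
    expect_lte(select_T_star(a, t1)$T_star, select_T_star(a, t2)$T_star)
    cc <- runif(1, 1e-3, 1e3)
    expect_identical(select_T_star(a, t1)$T_star,
                     select_T_star(cc * a, t1)$T_star)
  }
})

test_that("attention_matrix stacks records and traces the highlighted timestep", {
  u <- matrix(1 / 4, 3, 4)
  am <- attention_matrix(u)
  expect_equal(am$matrix, u)
  expect_equal(am$argmax, rep(4L, 3))            # ties go to the most recent

  # one-hot records marching backward give the slope -1 trace
  recs <- lapply(0:3, function(k) {
    r <- rep(0, 5); r[5 - k] <- 1; r
  })
  expect_equal(attention_matrix(recs)$argmax, c(5L, 4L, 3L, 2L))

  set.seed(2)
  rnd <- t(apply(matrix(runif(40), 8), 1, function(r) r / sum(r)))
  expect_equal(rowSums(attention_matrix(rnd)$matrix), rep(1, 8))
})

test_that("a 100% threshold keeps the full window and a full-length no-TAM retrain", {
  sess <- make_session(synthetic_config(n_bins = 300L, n_units = 6L,
                                        lag_window = 2L, seed = 3L))
  cfg <- decoder_config("rnn", n_layers = 1L, hidden_size = 4L,
                        batch_size = 32L, learning_rate = 2e-3,
                        epochs = 2L, seed = 9L)
  rep <- run_tts(sess, T_len = 6L, config = cfg,
                 split = split_spec(train_end = 240L), threshold = 100)
  expect_identical(rep$selection$T_star, 6L)
  expect_false(rep$decoder_retrained$use_tam)
  expect_identical(rep$decoder_retrained$T_len, 6L)
  # determinism: the same invocation reproduces the report
  rep2 <- run_tts(sess, T_len = 6L, config = cfg,
                  split = split_spec(train_end = 240L), threshold = 100)
  expect_identical(rep$metrics_full, rep2$metrics_full)
  expect_identical(rep$attention, rep2$attention)
})

test_that("plot_attention returns a ggplot heatmap", {
  set.seed(1)
  m <- t(apply(matrix(runif(60), 10), 1, function(r) r / sum(r)))
  p <- plot_attention(m)
  expect_s3_class(p, "ggplot")
})
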