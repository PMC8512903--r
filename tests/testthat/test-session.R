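test_that("session constructor enforces its invariants", {
  expect_error(
    binned_session(matrix(1, 50, 10), matrix(0, 49, 2)),
    "same bins"
  )
  expect_error(
    binned_session(matrix(-1, 5, 2), matrix(0, 5, 2)),
    "nonnegative"
  )
  expect_error(
    binned_session(matrix(1, 5, 2), matrix(0, 5, 2), bin_width = 0),
    "positive"
  )
  s <- binned_session(matrix(1, 50, 10), matrix(0, 50, 2))
  expect_equal(n_bins(s), 50L)
  expect_equal(n_units(s), 10L)
})

test_that("write/read round trip preserves a session bit for bit", {
  s <- tiny_session(nb = 100L, C = 5L)
  s$metadata <- list(lag_window = 4L, seed = 9L, note = "fixture")
  f <- withr::local_tempfile(fileext = ".csv")
  write_session(s, f)
  s2 <- read_session(f)
  expect_identical(s2$rates, s$rates)
  expect_identical(s2$kinematics, s$kinematics)
  expect_identical(s2$bin_width, s$bin_width)
  expect_identical(s2$session_id, s$session_id)
  expect_identical(s2$metadata$lag_window, 4L)
  expect_identical(s2$metadata$seed, 9L)
  expect_identical(s2$metadata$note, "fixture")
})

test_that("CSV sessions report their shapes and reject bad files", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_session(tiny_session(nb = 50L, C = 10L), f)
  s <- load_session(f)
  expect_equal(dim(s$rates), c(50L, 10L))
  expect_equal(dim(s$kinematics), c(50L, 2L))

  # a missing kinematic value breaks the equal-row invariant
  lines <- readLines(f)
  lines[length(lines)] <- sub("[^,]*$", "", lines[length(lines)])
  writeLines(lines, f)
  expect_error(read_session(f), "missing")

  expect_error(read_session("does-not-exist.csv"), "no such file")
  expect_error(read_session("x.h5"), "HDF5|no such file")
})

test_that("assemble_sequences produces exactly N - T + 1 aligned windows", {
  s <- tiny_session(nb = 50L)
  ds <- assemble_sequences(s, 10L)
  expect_equal(n_samples(ds), 41L)
  # first sample covers bins 1..10 with the target at bin 10
  expect_equal(ds$x[1, , ], s$rates[1:10, ])
  expect_equal(ds$y[1, ], s$kinematics[10, ])
  expect_equal(ds$clock_index[1], 10L)
  # sample k has clock index T + k - 1
  expect_equal(ds$clock_index, 10:50)
  # window row tau equals session bin clock - T + tau
  expect_equal(ds$x[17, 3, ], s$rates[17 + 3 - 1, ])

  expect_equal(n_samples(assemble_sequences(s, 1L)), 50L)
  expect_equal(assemble_sequences(s, 1L)$x[13, 1, ], s$rates[13, ])
  expect_equal(n_samples(assemble_sequences(s, 50L)), 1L)
  expect_error(assemble_sequences(s, 51L), "exceeds")
})

test_that("windowing is exact: last rows reproduce session bins T..N", {
  s <- tiny_session(nb = 40L, C = 3L)
  for (T_len in c(1L, 7L, 40L)) {
    ds <- assemble_sequences(s, T_len)
    last_rows <- ds$x[, T_len, , drop = TRUE]
    expect_equal(
      matrix(last_rows, ncol = 3L),
      s$rates[T_len:40L, , drop = FALSE]
    )
  }
})

test_that("truncating long windows to their last T* columns equals direct assembly", {
  s <- tiny_session(nb = 30L, C = 4L)
  T_big <- 9L
  ds_big <- assemble_sequences(s, T_big)
  for (T_small in c(1L, 3L, 9L)) {
    ds_small <- assemble_sequences(s, T_small)
    # align on common clock indices
    keep <- ds_small$clock_index >= T_big
    trunc <- ds_big$x[, (T_big - T_small + 1L):T_big, , drop = FALSE]
    expect_equal(unname(trunc), unname(ds_small$x[keep, , , drop = FALSE]))
    expect_equal(ds_big$y, ds_small$y[keep, , drop = FALSE])
  }
})

test_that("prefix split is a contiguous partition of the session", {
  s <- tiny_session(nb = 100L)
  sp <- split_session(s, split_spec(train_end = 80L))
  expect_equal(n_bins(sp$train), 80L)
  expect_equal(n_bins(sp$test), 20L)
  expect_equal(rbind(sp$train$rates, sp$test$rates), s$rates)
  expect_equal(rbind(sp$train$kinematics, sp$test$kinematics), s$kinematics)
  expect_error(split_session(s, split_spec(train_end = 100L)), "inside")
  expect_error(split_session(s, split_spec(train_end = 0L)), "inside")

  big <- binned_session(matrix(1, 6000, 2), matrix(0, 6000, 2))
  sp2 <- split_session(big, split_spec(train_end = 5000L))
  expect_equal(n_bins(sp2$train), 5000L)
  expect_equal(n_bins(sp2$test), 1000L)
})

test_that("kfold split gives contiguous folds with sizes differing by at most 1", {
  s <- binned_session(matrix(1, 1473, 1), matrix(0, 1473, 1))
  sp <- split_session(s, split_spec(policy = "kfold", n_folds = 10L))
  sizes <- lengths(sp$folds)
  expect_length(sp$folds, 10L)
  expect_lte(diff(range(sizes)), 1L)
  expect_equal(sort(unlist(sp$folds)), 1:1473)
})
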