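test_that("R2 follows the variance form of the residual", {
  y <- c(0, 1, 2, 3)
  expect_equal(r_squared(y, y), 1)
  # constant-offset residual has zero variance: a documented property of the
  # variance form (differs from the SS-residual convention)
  expect_equal(r_squared(y, y + 5), 1)
  expect_equal(r_squared(y, rep(0, 4)), 0)
  # mean predictor scores exactly 0
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_error(r_squared(rep(2, 5), rnorm(5)), "constant")
  expect_error(r_squared(1:3, 1:4), "shape")
})

test_that("CC reproduces hand-computed and affine-invariance cases", {
  y <- c(1, 2, 3, 4)
  expect_equal(pearson_cc(y, 2 * y + 3), 1)
  expect_equal(pearson_cc(y, -y), -1)
  expect_equal(pearson_cc(y, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_cc(y, rep(1, 4)), "constant")
})

test_that("metric identities hold property-style over random data", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    y <- rnorm(n)
    yhat <- rnorm(n)
    a <- runif(1, 0.1, 3)
    b <- rnorm(1)
    # CC invariant to positive affine transforms of either argument
    expect_equal(pearson_cc(y, a * yhat + b), pearson_cc(y, yhat))
    expect_equal(pearson_cc(a * y + b, yhat), pearson_cc(y, yhat))
    expect_lte(abs(pearson_cc(y, yhat)), 1)
    # R2 invariant to constant shifts of the prediction
    expect_equal(r_squared(y, yhat + b), r_squared(y, yhat))
    expect_lte(r_squared(y, yhat), 1)
    # agreement with independent scalar-loop evaluations
    r2_loop <- {
      res <- y - yhat
      vres <- sum((res - sum(res) / n)^2) / n
      vy <- sum((y - sum(y) / n)^2) / n
      1 - vres / vy
    }
    expect_equal(r_squared(y, yhat), r2_loop, tolerance = 1e-12)
    cc_loop <- {
      cv <- sum((y - mean(y)) * (yhat - mean(yhat))) / n
      cv / sqrt(sum((y - mean(y))^2) / n) / sqrt(sum((yhat - mean(yhat))^2) / n)
    }
    expect_equal(pearson_cc(y, yhat), cc_loop, tolerance = 1e-12)
    # and with the standard correlation routine
    expect_equal(pearson_cc(y, yhat), stats::cor(y, yhat), tolerance = 1e-12)
  }
})

test_that("matrix metrics aggregate per dimension and on average", {
  set.seed(8)
  y <- matrix(rnorm(40), 20, 2)
  yhat <- y + matrix(rnorm(40, sd = 0.3), 20, 2)
  per <- r_squared(y, yhat, "per_dim")
  expect_length(per, 2)
  expect_equal(r_squared(y, yhat, "mean"), mean(per))
  rep <- metric_report(y, yhat)
  expect_equal(rep$r2_mean, mean(rep$r2))
  expect_equal(rep$cc_mean, mean(rep$cc))
  expect_equal(rep$n_test, 20L)
})

test_that("compare_groups runs the normality/omnibus/post-hoc workflow", {
  # identical groups: omnibus near 1, no stars
  g <- matrix(rep(rnorm(10, sd = 1), 3), ncol = 3)
  cmp <- compare_groups(g)
  expect_gte(cmp$friedman_p, 0.99)
  expect_true(all(cmp$pairwise$stars == ""))

  # deterministic shifts: omnibus rejects strongly
  base <- 1:10
  cmp2 <- compare_groups(cbind(a = base, b = base + 10, c = base + 20))
  expect_lt(cmp2$friedman_p, 0.01)
  expect_equal(cmp2$friedman_p,
               stats::friedman.test(cbind(base, base + 10, base + 20))$p.value)
  expect_true(all(cmp2$pairwise$stars != ""))
  expect_length(cmp2$normality_p, 3)

  # two conditions: Friedman skipped, Wilcoxon only
  cmp3 <- compare_groups(cbind(x = base, y = base + 5))
  expect_true(is.na(cmp3$friedman_p))
  expect_match(cmp3$note, "Wilcoxon")
  expect_equal(nrow(cmp3$pairwise), 1L)

  expect_error(compare_groups(list(a = 1:5, b = 1:4)), "equal length")
  expect_error(compare_groups(matrix(1, 3, 1)), "two conditions")
})
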