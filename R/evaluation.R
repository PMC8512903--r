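var_pop <- function(x) mean((x - mean(x))^2)

check_paired <- function(y, yhat) {
  y <- as.matrix(y)
  yhat <- as.matrix(yhat)
  if (!identical(dim(y), dim(yhat))) {
    stop("`y` and `yhat` must have the same shape", call. = FALSE)
  }
  if (nrow(y) < 2L) stop("need at least 2 samples", call. = FALSE)
  list(y = y, yhat = yhat)
}

#' Coefficient of determination (variance form)
#'
#' `R2 = 1 - Var(y - yhat) / Var(y)` with `Var` the population variance of
#' the mean-removed residual. Because the residual is mean-removed, this
#' form is invariant to adding a constant to `yhat` (a constant offset gives
#' `R2 = 1`), which differs from the sum-of-squared-residuals convention;
#' the property is intentional and tested. A predictor equal to `mean(y)`
#' scores exactly 0.
#'
#' @param y,yhat Numeric vectors or equally shaped matrices (columns =
#'   kinematic dimensions).
#' @param aggregate For matrix input: `"mean"` (unweighted mean over
#'   dimensions, the default), `"per_dim"` (one value per column) or
#'   `"concat"` (treat all columns as one long vector).
#' @return Numeric scalar (or vector for `"per_dim"`); always `<= 1`.
#' @export
r_squared <- function(y, yhat, aggregate = c("mean", "per_dim", "concat")) {
  aggregate <- match.arg(aggregate)
  p <- check_paired(y, yhat)
  if (aggregate == "concat") {
    p <- list(y = matrix(as.numeric(p$y)), yhat = matrix(as.numeric(p$yhat)))
  }
  vals <- vapply(seq_len(ncol(p$y)), function(j) {
    yj <- p$y[, j]
    if (var_pop(yj) == 0) {
      stop("R2 is undefined for a constant target", call. = FALSE)
    }
    1 - var_pop(yj - p$yhat[, j]) / var_pop(yj)
  }, numeric(1))
  switch(aggregate, mean = mean(vals), per_dim = vals, concat = vals[1])
}

#' Pearson correlation coefficient
#'
#' `CC = cov(y, yhat) / (sd(y) sd(yhat))`; invariant to positive affine
#' transforms of either argument and bounded in `[-1, 1]`.
#'
#' @inheritParams r_squared
#' @return Numeric scalar (or vector for `"per_dim"`).
#' @export
pearson_cc <- function(y, yhat, aggregate = c("mean", "per_dim", "concat")) {
  aggregate <- match.arg(aggregate)
  p <- check_paired(y, yhat)
  if (aggregate == "concat") {
    p <- list(y = matrix(as.numeric(p$y)), yhat = matrix(as.numeric(p$yhat)))
  }
  vals <- vapply(seq_len(ncol(p$y)), function(j) {
    yj <- p$y[, j]
    pj <- p$yhat[, j]
    if (var_pop(yj) == 0 || var_pop(pj) == 0) {
      stop("CC is undefined for constant inputs", call. = FALSE)
    }
    mean((yj - mean(yj)) * (pj - mean(pj))) /
      (sqrt(var_pop(yj)) * sqrt(var_pop(pj)))
  }, numeric(1))
  switch(aggregate, mean = mean(vals), per_dim = vals, concat = vals[1])
}

#' Decoding metric report
#'
#' Per-dimension and averaged R2 and CC for a set of predictions. The
#' headline scalars are the unweighted means over kinematic dimensions;
#' the per-dimension values are always carried along.
#'
#' @param y Targets, `n x D`.
#' @param yhat Predictions, same shape.
#' @return An object of class `metric_report`: list with `r2` (per
#'   dimension), `r2_mean`, `cc`, `cc_mean`, `n_test`.
#' @export
metric_report <- function(y, yhat) {
  p <- check_paired(y, yhat)
  structure(
    list(
      r2 = r_squared(p$y, p$yhat, "per_dim"),
      r2_mean = r_squared(p$y, p$yhat, "mean"),
      cc = pearson_cc(p$y, p$yhat, "per_dim"),
      cc_mean = pearson_cc(p$y, p$yhat, "mean"),
      n_test = nrow(p$y)
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> n=%d  R2 = %.3f (%s)  CC = %.3f (%s)\n",
              x$n_test, x$r2_mean, paste(sprintf("%.3f", x$r2), collapse = ", "),
              x$cc_mean, paste(sprintf("%.3f", x$cc), collapse = ", ")))
  invisible(x)
}

significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) "" else if (pi < 0.001) "***"
    else if (pi < 0.01) "**" else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Compare paired groups of decoding scores
#'
#' The statistical workflow used for comparing decoder conditions: a
#' Shapiro-Wilk normality check per group, a Friedman omnibus test over the
#' paired conditions, and post hoc pairwise Wilcoxon signed-rank tests with
#' significance stars at p < 0.05 / 0.01 / 0.001. With only two conditions
#' the Friedman test is skipped and the Wilcoxon test stands alone (noted in
#' the result). P-values are reported raw by default; `p_adjust = "holm"`
#' applies a Holm correction to the pairwise tests.
#'
#' @param groups Numeric matrix (`n` paired observations x `k` conditions)
#'   or a named list of equal-length numeric vectors.
#' @param p_adjust `"none"` (default, raw p-values) or `"holm"`.
#' @return An object of class `stat_comparison`: list with `normality_p`
#'   (Shapiro-Wilk per group; NA when n < 3), `friedman_p`, `pairwise`
#'   (data frame with `group1`, `group2`, `p`, `stars`), `n`, `k`, `note`.
#' @export
compare_groups <- function(groups, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (is.list(groups) && !is.data.frame(groups)) {
    lens <- lengths(groups)
    if (length(unique(lens)) != 1L) {
      stop("groups must be paired samples of equal length", call. = FALSE)
    }
    groups <- do.call(cbind, groups)
  }
  groups <- as.matrix(groups)
  k <- ncol(groups)
  n <- nrow(groups)
  if (k < 2L) stop("need at least two conditions", call. = FALSE)
  if (n < 2L) stop("need at least two paired observations", call. = FALSE)
  if (is.null(colnames(groups))) colnames(groups) <- paste0("g", seq_len(k))

  normality_p <- vapply(seq_len(k), function(j) {
    x <- groups[, j]
    if (n < 3L || n > 5000L || stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  names(normality_p) <- colnames(groups)

  note <- NULL
  friedman_p <- NA_real_
  if (k >= 3L) {
    friedman_p <- stats::friedman.test(groups)$p.value
    # fully tied data yields a 0/0 statistic; read it as "no effect"
    if (!is.finite(friedman_p)) friedman_p <- 1
  } else {
    note <- "two conditions: Friedman omnibus skipped, Wilcoxon only"
  }

  pairs <- utils::combn(k, 2L)
  pw <- data.frame(
    group1 = colnames(groups)[pairs[1, ]],
    group2 = colnames(groups)[pairs[2, ]],
    p = apply(pairs, 2L, function(ij) {
      d <- groups[, ij[1]] - groups[, ij[2]]
      if (all(d == 0)) return(NA_real_)
      suppressWarnings(
        stats::wilcox.test(groups[, ij[1]], groups[, ij[2]],
                           paired = TRUE, exact = FALSE)$p.value
      )
    }),
    stringsAsFactors = FALSE
  )
  if (p_adjust == "holm") pw$p <- stats::p.adjust(pw$p, method = "holm")
  pw$stars <- significance_stars(pw$p)

  structure(
    list(normality_p = normality_p, friedman_p = friedman_p,
         pairwise = pw, n = n, k = k, note = note,
         p_adjust = p_adjust),
    class = "stat_comparison"
  )
}

#' @export
print.stat_comparison <- function(x, ...) {
  cat(sprintf("<stat_comparison> %d conditions, %d paired observations\n",
              x$k, x$n))
  if (!is.na(x$friedman_p)) {
    cat(sprintf("  Friedman omnibus p = %.4g %s\n", x$friedman_p,
                significance_stars(x$friedman_p)))
  }
  if (!is.null(x$note)) cat("  ", x$note, "\n", sep = "")
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("  %s vs %s: p = %.4g %s\n",
                x$pairwise$group1[i], x$pairwise$group2[i],
                x$pairwise$p[i], x$pairwise$stars[i]))
  }
  invisible(x)
}
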