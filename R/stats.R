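#' Group effect adjusted for a motion covariate
#'
#' Fits ordinary least squares `y ~ group + covariate` and reports the
#' two-sided t-test of the group coefficient (df = s - 3). This is the
#' standard way to compare a fingerprinting measure between drug and placebo
#' groups while controlling for head motion.
#'
#' @param y Per-subject outcome values.
#' @param group Binary group indicator (factor, logical, or 0/1); the
#'   reported effect is for the second level (coded 1).
#' @param covariate Per-subject scalar covariate (e.g. motion-artifact
#'   volume count).
#' @return A `test_result` list: `kind`, `estimate`, `statistic`, `df`, `p`.
#' @export
group_effect_with_covariate <- function(y, group, covariate) {
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(as.logical(group))
  assert_that(length(unique(g)) == 2, "group must have exactly 2 levels")
  assert_that(min(table(g)) >= 2, "need at least 2 subjects per group")
  fit <- stats::lm(y ~ g + covariate)
  assert_that(!any(is.na(stats::coef(fit))),
              "rank-deficient design: covariate collinear with group")
  sm <- summary(fit)$coefficients
  structure(list(kind = "group_plus_covariate",
                 estimate = unname(sm["g", "Estimate"]),
                 statistic = unname(sm["g", "t value"]),
                 df = fit$df.residual,
                 p = unname(sm["g", "Pr(>|t|)"])),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result %s> stat = %.4g, df = %s, p = %.4g\n",
              x$kind, x$statistic, format(x$df), x$p))
  invisible(x)
}

#' Classical t-tests (paired, one-sample, two-sample)
#'
#' Thin wrapper around [stats::t.test()] returning the package's uniform
#' `test_result` shape; all tests are two-sided. The two-sample variant
#' pools variances (classical equal-variance t).
#'
#' @param kind `"paired"`, `"one_sample"` or `"two_sample"`.
#' @param x First sample.
#' @param y Second sample (paired/two-sample kinds).
#' @param mu Null mean for the one-sample kind.
#' @return A `test_result` list.
#' @export
t_test <- function(kind = c("paired", "one_sample", "two_sample"),
                      x, y = NULL, mu = 0) {
  kind <- match.arg(kind)
  degenerate <- function(v, center) {
    # constant data at the null value: t = 0, p = 1 rather than an error
    list(estimate = mean(v), statistic = 0,
         parameter = length(v) - 1, p.value = 1)
  }
  tt <- switch(kind,
    paired = if (stats::sd(x - y) == 0 && mean(x - y) == 0) {
      degenerate(x - y, 0)
    } else stats::t.test(x, y, paired = TRUE),
    one_sample = if (stats::sd(x) == 0 && mean(x) == mu) {
      degenerate(x, mu)
    } else stats::t.test(x, mu = mu),
    two_sample = stats::t.test(x, y, var.equal = TRUE))
  structure(list(kind = kind, estimate = unname(tt$estimate)[1],
                 statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value),
            class = "test_result")
}

#' Pearson correlation with a two-sided p-value
#'
#' Reports r together with the p-value of the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param a,b Equal-length numeric vectors (length >= 4).
#' @return A `test_result` list with an extra element `r`.
#' @export
pearson_with_p <- function(a, b) {
  assert_that(length(a) == length(b), "vectors must have equal length")
  assert_that(length(a) >= 4, "need at least 4 observations")
  assert_that(stats::sd(a) > 0 && stats::sd(b) > 0,
              "zero variance: correlation undefined")
  ct <- stats::cor.test(a, b, method = "pearson")
  structure(list(kind = "pearson", r = unname(ct$estimate),
                 estimate = unname(ct$estimate),
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value),
            class = "test_result")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, clipped at 1
#' (delegates to [stats::p.adjust()]).
#'
#' @param pvals Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  assert_that(all(is.finite(pvals) & pvals >= 0 & pvals <= 1),
              "p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
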