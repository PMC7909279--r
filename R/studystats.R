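#' Two-sample test for equality of proportions
#'
#' Continuity-corrected chi-square test and Wald confidence interval for
#' `p1 - p2`, via `stats::prop.test` (Yates correction, unpooled SE in the
#' CI with the correction capped at |diff|).
#'
#' @param x1,x2 success counts.
#' @param n1,n2 group sizes.
#' @param conf.level confidence level (default 0.95).
#' @return list of class `prop_test_result`: `statistic` (chi-square),
#'   `p.value`, `conf.int` (difference scale), `estimate` (p1, p2).
#' @examples
#' r <- prop_test_2sample(19, 45, 9, 45)
#' round(r$conf.int, 3)  # 0.014 0.430
#' @export
prop_test_2sample <- function(x1, n1, x2, n2, conf.level = 0.95) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pt <- suppressWarnings(
    prop.test(c(x1, x2), c(n1, n2), conf.level = conf.level))
  structure(list(statistic = unname(pt$statistic),
                 p.value = pt$p.value,
                 conf.int = as.numeric(pt$conf.int),
                 estimate = unname(pt$estimate)),
            class = "prop_test_result")
}

#' F-test for equality of variances from summary statistics
#'
#' Two-sided F-test of `v1 / v2` given sample variances and their degrees
#' of freedom (the inputs available from reported summaries, where the raw
#' vectors are not).
#'
#' @param v1,v2 sample variances (> 0).
#' @param df1,df2 degrees of freedom (>= 1).
#' @param conf.level confidence level for the variance-ratio CI.
#' @return list with `statistic` (F), `p.value` (two-sided), `conf.int`
#'   (ratio scale).
#' @export
var_f_test <- function(v1, df1, v2, df2, conf.level = 0.95) {
  stopifnot(v1 > 0, v2 > 0, df1 >= 1, df2 >= 1)
  f <- v1 / v2
  p <- 2 * min(pf(f, df1, df2), pf(f, df1, df2, lower.tail = FALSE))
  p <- min(p, 1)
  alpha <- 1 - conf.level
  ci <- c(f / qf(1 - alpha / 2, df1, df2), f / qf(alpha / 2, df1, df2))
  list(statistic = f, p.value = p, conf.int = ci)
}

#' Two-predictor linear regression A ~ M + P
#'
#' Least-squares fit of an accuracy response on the pairwise distance
#' between the mixed haplotypes (M) and the minimum distance between the
#' mixture and the reference panel (P), with t-tests on the coefficients.
#'
#' @param y response (e.g. per-mixture phasing error count or accuracy).
#' @param m,p the two predictors.
#' @return list of class `ols2_result`: `coefficients` (estimate, SE,
#'   t value, p value for intercept, m, p), `r_squared`, `fit`.
#' @export
ols2 <- function(y, m, p) {
  stopifnot(length(y) == length(m), length(y) == length(p),
            length(y) >= 4L)
  fit <- lm(y ~ m + p)
  if (any(is.na(coef(fit)))) stop("singular design (collinear predictors)")
  sm <- summary(fit)
  structure(list(coefficients = sm$coefficients,
                 r_squared = sm$r.squared, fit = fit),
            class = "ols2_result")
}
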