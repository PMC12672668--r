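#' Paired t-test with paired effect size
#'
#' Classical paired t-test on condition differences, reporting the paired
#' (difference-score) effect size `d_z = mean(diff) / sd(diff) = t / sqrt(n)`,
#' the standardization consistent with reporting conventions for paired
#' designs.
#'
#' @param x,y Equal-length numeric vectors (paired observations), no
#'   missing values, `n >= 3`.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`; the direction
#'   refers to `x - y`.
#' @return One-row tibble with `t`, `df`, `p`, `d_z`, `n`, `mean_diff`,
#'   `sd_diff`, `alternative`.
#' @export
paired_test <- function(x, y,
                        alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (anyNA(x) || anyNA(y)) abort("missing values are not allowed")
  diffs <- x - y
  if (stats::sd(diffs) == 0) {
    abort("zero variance of differences: paired t-test undefined")
  }
  ht <- t.test(x, y, paired = TRUE, alternative = alternative)
  n <- length(x)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, d_z = unname(ht$statistic) / sqrt(n), n = n,
    mean_diff = mean(diffs), sd_diff = stats::sd(diffs),
    alternative = alternative
  )
}

#' Pearson correlation with degrees of freedom and p-value
#'
#' Product-moment correlation, `df = n - 2`, two-sided p from the t
#' transform (as reported in correlation write-ups `r(df) = ..., p = ...`).
#'
#' @param x,y Numeric vectors of equal length, `n >= 4`.
#' @return One-row tibble with `r`, `df`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 4) abort("need at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("constant vector: correlation undefined")
  }
  ht <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ht$estimate), df = unname(ht$parameter),
                 p = ht$p.value, n = length(x))
}

#' Analytic power of a paired t-test
#'
#' One- or two-sided noncentral-t power at a given paired effect size and
#' sample size.
#'
#' @param d_z Paired (difference-score) effect size.
#' @param n Number of pairs.
#' @param alpha Significance level (default 0.05).
#' @param sided `"one"` or `"two"`.
#' @return Power in (0, 1).
#' @export
paired_t_power <- function(d_z, n, alpha = 0.05,
                           sided = c("one", "two")) {
  sided <- match.arg(sided)
  a <- if (sided == "one") alpha else alpha / 2
  ncp <- d_z * sqrt(n)
  crit <- qt(1 - a, df = n - 1)
  pw <- 1 - pt(crit, df = n - 1, ncp = ncp)
  if (sided == "two") pw <- pw + pt(-crit, df = n - 1, ncp = ncp)
  pw
}

#' Sample size for a paired t-test from a between-condition effect size
#'
#' Converts a between-condition standardized effect `d` and the correlation
#' `r` between conditions to the paired effect size
#' `d_z = d / sqrt(2 (1 - r))`, then finds the required number of pairs.
#' `method = "exact"` returns the smallest `N` whose noncentral-t power
#' (ncp `d_z * sqrt(N)`, df `N - 1`) reaches the target. `method =
#' "approx"` uses the classical normal-approximation formula with
#' small-sample correction, `N = ceiling(((z_alpha + z_beta) / d_z)^2 +
#' z_alpha^2 / 2)`, common in planning software; the two can differ by one
#' participant when the exact power at the approximate `N` is marginally
#' below target.
#'
#' @param d_between Between-condition effect size (> 0).
#' @param r_between Correlation between conditions (|r| < 1).
#' @param power Target power in (0, 1) (default 0.9).
#' @param alpha Significance level (default 0.05).
#' @param sided `"one"` or `"two"`.
#' @param method `"exact"` (noncentral t, default) or `"approx"`.
#' @return Integer sample size (>= 3).
#' @examples
#' paired_sample_size(0.95, 0.44, method = "approx") # 12
#' paired_sample_size(0.95, 0.44, method = "exact")  # 13
#' @export
paired_sample_size <- function(d_between, r_between, power = 0.9,
                               alpha = 0.05, sided = c("one", "two"),
                               method = c("exact", "approx")) {
  sided <- match.arg(sided)
  method <- match.arg(method)
  stopifnot(power > 0, power < 1, alpha > 0, alpha < 1,
            abs(r_between) < 1)
  d_z <- d_between / sqrt(2 * (1 - r_between))
  if (d_z <= 0) abort("effect size must be positive")
  a <- if (sided == "one") alpha else alpha / 2
  if (method == "approx") {
    za <- stats::qnorm(1 - a)
    zb <- stats::qnorm(power)
    return(max(3L, as.integer(ceiling(((za + zb) / d_z)^2 + za^2 / 2))))
  }
  n <- 3L
  while (paired_t_power(d_z, n, alpha, sided) < power) {
    n <- n + 1L
    if (n > 1e6) abort("sample size search did not terminate")
  }
  n
}
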