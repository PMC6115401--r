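#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two groups of values with the Wilcoxon (Mann-Whitney) rank-sum
#' test. The reported `statistic` is the rank sum of the first group `a`
#' (so it lies in `[n_a(n_a+1)/2, n_a*n_b + n_a(n_a+1)/2]`), the convention
#' used for the rank-sum statistics quoted throughout the package's outputs.
#' The p-value is exact (full permutation null) when the pooled sample size
#' is at most `exact_threshold` and there are no ties; otherwise the normal
#' approximation with tie correction and 0.5 continuity correction is used.
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param exact_threshold Largest pooled sample size for which the exact
#'   null distribution is enumerated (default 25).
#' @return An object of class `"rank_test"`: a list with `statistic` (rank
#'   sum of `a`), `u_statistic` (Mann-Whitney U of `a`), `p_value`, `n_a`,
#'   `n_b` and `exact` (logical, whether the exact null was used).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxon_rank_sum <- function(a, b, exact_threshold = 25L) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty; the rank-sum test is undefined otherwise")
  if (anyNA(a) || anyNA(b))
    stop("missing values are not allowed in rank-sum input")
  n_a <- length(a)
  n_b <- length(b)
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && (n_a + n_b) <= exact_threshold
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE)
  )
  structure(
    list(statistic = unname(res$statistic) + n_a * (n_a + 1) / 2,
         u_statistic = unname(res$statistic),
         p_value = min(res$p.value, 1),
         n_a = n_a, n_b = n_b, exact = use_exact),
    class = "rank_test"
  )
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf(
    "Two-sided Wilcoxon rank sum test (%s)\n  rank-sum statistic (group A) = %g, n = %d vs %d, p = %.4g\n",
    if (x$exact) "exact" else "normal approximation, tie/continuity corrected",
    x$statistic, x$n_a, x$n_b, x$p_value))
  invisible(x)
}

#' Pearson or Spearman correlation coefficient
#'
#' Product-moment correlation of two equal-length vectors; the Spearman
#' variant is the Pearson coefficient computed on mid-ranks. Constant
#' input vectors are rejected because the coefficient is undefined.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
cor_coef <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 paired observations are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation is undefined for a constant vector")
  stats::cor(x, y, method = method)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1, returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact two-sided confidence interval for a binomial proportion, in the
#' beta-quantile form; the interval endpoints hit 0 and 1 at the boundary
#' counts.
#'
#' @param successes Number of successes (`0 <= successes <= n`).
#' @param n Number of trials (`n >= 1`).
#' @param confidence Confidence level, default 0.95.
#' @return An object of class `"interval_estimate"`: list with `point`
#'   (`successes/n`), `lower`, `upper`, `confidence`, `successes`, `n`.
#' @examples
#' clopper_pearson(7, 25)
#' @export
clopper_pearson <- function(successes, n, confidence = 0.95) {
  if (length(successes) != 1L || length(n) != 1L || is.na(successes) || is.na(n))
    stop("successes and n must be single non-missing counts")
  if (n < 1 || successes < 0 || successes > n)
    stop("require 0 <= successes <= n and n >= 1")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)")
  ci <- stats::binom.test(round(successes), round(n),
                          conf.level = confidence)$conf.int
  structure(
    list(point = successes / n, lower = ci[1], upper = ci[2],
         confidence = confidence, successes = successes, n = n),
    class = "interval_estimate"
  )
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%d/%d = %.3f, %g%% Clopper-Pearson CI [%.3f, %.3f]\n",
              x$successes, x$n, x$point, 100 * x$confidence,
              x$lower, x$upper))
  invisible(x)
}
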