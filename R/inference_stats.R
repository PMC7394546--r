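#' Proportion with Wilson 95% confidence interval
#'
#' Percentages are reported on the 0-100 scale to match figure labels; the
#' 95% interval is the Wilson score interval, which remains sensible at the
#' extreme proportions (a few percent, or close to 90%) that occur in comet
#' event tables.
#'
#' @param k Number of successes.
#' @param n Number of trials (>= 1).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `proportion_result`: list with `k`, `n`,
#'   `percent`, `ci_low`, `ci_high` (all percentages) and `method`.
#' @export
proportion <- function(k, n, conf_level = 0.95) {
  if (length(k) != 1 || length(n) != 1 || !is.finite(k) || !is.finite(n)) {
    stop("k and n must be single finite numbers")
  }
  if (n < 1) stop("n must be >= 1")
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  p <- k / n
  z <- qnorm(1 - (1 - conf_level) / 2)
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  structure(
    list(k = as.integer(k), n = as.integer(n),
         percent = 100 * p,
         ci_low = 100 * max(centre - half, 0),
         ci_high = 100 * min(centre + half, 1),
         conf_level = conf_level, method = "wilson"),
    class = "proportion_result")
}

#' @export
print.proportion_result <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (95%% CI %.1f-%.1f%%, %s)\n",
              x$k, x$n, x$percent, x$ci_low, x$ci_high, x$method))
  invisible(x)
}

.chisq_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = as.numeric(statistic), df = as.integer(df),
                 p_value = as.numeric(p_value), method = method),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  p <- if (x$p_value < 0.001) "p < 0.001" else
    paste0("p = ", signif(x$p_value, 2))
  cat(sprintf("chi-squared = %.4g, df = %d, %s (%s)\n",
              x$statistic, x$df, p, x$method))
  invisible(x)
}

#' One-way chi-squared goodness-of-fit test
#'
#' Tests observed bin counts against expected proportions (for example,
#' folded comet angles against the uniform distribution expected for random
#' growth directions). Delegates to [stats::chisq.test()].
#'
#' @param observed Vector of non-negative counts.
#' @param expected_proportions Probabilities of the same length, summing
#'   to 1; every expected count must be positive.
#' @return A `chisq_result` with `statistic`, `df` and `p_value`.
#' @export
chisq_gof <- function(observed, expected_proportions) {
  if (length(observed) != length(expected_proportions)) {
    stop("observed and expected_proportions must have equal length")
  }
  if (any(observed < 0)) stop("negative observed count")
  if (abs(sum(expected_proportions) - 1) > 1e-9) {
    stop("expected proportions must sum to 1")
  }
  if (any(expected_proportions <= 0)) stop("zero expected count")
  res <- suppressWarnings(stats::chisq.test(observed, p = expected_proportions))
  .chisq_result(res$statistic, res$parameter, res$p.value, "oneway_chi2_gof")
}

#' Compare two proportions with a 2x2 chi-squared test
#'
#' Pearson chi-squared on the 2x2 table of successes and failures, without
#' continuity correction (the uncorrected test reproduces the reported
#' comparisons between comet event proportions; the correction is a
#' documented non-choice). Degenerate margins (all successes or all failures
#' in both groups) return p = 1 by convention with a message.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return A `chisq_result` with `df = 1`.
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("both group sizes must be >= 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) stop("counts must satisfy 0 <= k <= n")
  if ((k1 + k2 == 0) || (k1 + k2 == n1 + n2)) {
    message("degenerate 2x2 margins (all successes or all failures); p = 1")
    return(.chisq_result(0, 1, 1, "pearson_chi2_nocorrection"))
  }
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  .chisq_result(res$statistic, 1, res$p.value, "pearson_chi2_nocorrection")
}

#' Exact binomial upper tail
#'
#' Exact probability of observing `k` or more successes in `n` trials at
#' success probability `p0`, summed term by term -- e.g. the chance of the
#' observed skew of stack resultants between the upper (towards the axon)
#' and lower (away from the axon) quadrants under a symmetric null
#' (`p0 = 0.5`).
#'
#' @param k Observed successes (0 <= k <= n).
#' @param n Trials.
#' @param p0 Null success probability in (0, 1).
#' @return `P(X >= k)` under `Binomial(n, p0)`.
#' @export
binomial_upper_tail <- function(k, n, p0) {
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  if (k == 0) return(1)
  sum(dbinom(seq(k, n), n, p0))
}
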