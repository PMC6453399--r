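#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# Exact small-sample significance of classification accuracy vs chance.
# With 10 trials, even 8/10 correct (80%) is not significant at the 5%
# level against a fair coin: P[X >= 8] = 56/1024 = 0.0546875.
# ---------------------------------------------------------------------------

#' Exact binomial test of classification accuracy against chance
#'
#' Computes the exact binomial tail probability of observing `k` or more
#' correct answers out of `n` under `Binomial(n, chance)` (one-sided
#' "greater" by default, matching the scientific claim "above chance"; a
#' two-sided variant using the standard small-likelihood rule is
#' available). No normal approximation is used. Also reports the
#' two-sided Clopper-Pearson interval for the accuracy at level
#' `1 - alpha`.
#'
#' @param k correct count, `0 <= k <= n`.
#' @param n trial count, `n >= 1`.
#' @param chance chance level in `(0, 1)` (0.5 for balanced yes/no).
#' @param alpha significance level (default 0.05).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return a [ChanceTestResult-class].
#' @examples
#' accuracyBinomialTest(8, 10)   # p = 0.0546875: 80% on 10 trials is not enough
#' accuracyBinomialTest(10, 10)  # p = 1/1024
#' @export
accuracyBinomialTest <- function(k, n, chance = 0.5, alpha = 0.05,
                                 alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      k != round(k) || n != round(n) || n < 1 || k < 0 || k > n)
    stopf("invalid counts: need integers 0 <= k <= n with n >= 1 (got k = %s, n = %s)",
          format(k), format(n))
  if (!is.finite(chance) || chance <= 0 || chance >= 1)
    stopf("chance must lie strictly inside (0, 1), got %s", format(chance))
  k <- as.integer(k); n <- as.integer(n)
  if (alternative == "greater") {
    p <- stats::pbinom(k - 1L, n, chance, lower.tail = FALSE)
  } else {
    # standard exact two-sided rule: sum the probabilities of all outcomes
    # no more likely than the observed one
    d <- stats::dbinom(0:n, n, chance)
    p <- min(1, sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
  }
  ci <- c(if (k == 0L) 0 else stats::qbeta(alpha / 2, k, n - k + 1),
          if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k))
  methods::new("ChanceTestResult", k = k, n = n, chance = chance,
               pValue = p, alternative = alternative, ci = ci,
               alpha = alpha, significant = p < alpha)
}

#' Smallest trial count at which an accuracy claim reaches significance
#'
#' Searches n = 1, 2, ... for the smallest trial count such that
#' achieving `ceiling(targetAccuracy * n)` correct answers has exact
#' binomial tail probability below `alpha` against `chance`. Quantifies
#' why accuracy claims resting on very few trials (e.g. 10) carry no
#' statistical weight: perfect decoding needs at least 5 trials to beat
#' a fair coin at the 5% level, and 80% decoding needs far more.
#'
#' @param targetAccuracy claimed accuracy, `chance < targetAccuracy <= 1`.
#' @param chance chance level in `(0, 1)`.
#' @param alpha significance level.
#' @param maxN search cap (error if exceeded).
#' @return smallest qualifying integer n.
#' @examples
#' minTrialsForSignificance(1.0)  # 5: p = 1/32 at n = 5, 1/16 at n = 4
#' minTrialsForSignificance(0.8)
#' @export
minTrialsForSignificance <- function(targetAccuracy, chance = 0.5,
                                     alpha = 0.05, maxN = 100000L) {
  if (!is.finite(chance) || chance <= 0 || chance >= 1)
    stopf("chance must lie strictly inside (0, 1)")
  if (!is.finite(targetAccuracy) || targetAccuracy <= chance ||
      targetAccuracy > 1)
    stopf("targetAccuracy must exceed chance (%g) and be <= 1: an accuracy at or below chance can never be significant",
          chance)
  for (n in seq_len(maxN)) {
    k <- ceiling(targetAccuracy * n)
    if (stats::pbinom(k - 1, n, chance, lower.tail = FALSE) < alpha)
      return(as.integer(n))
  }
  stopf("no n <= %d reaches significance", maxN)
}
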