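# Two-sided Wilcoxon rank-sum (Mann-Whitney) test.
#
# The association engine calls this for every region-drug contrast, usually
# with a small mutated group against a large comparison group, so the exact
# path is restricted to the regime where enumeration is cheap and the null
# distribution is free of ties.

#' Two-sided Wilcoxon rank-sum test
#'
#' Compares two samples by ranks. When both groups have at most 8
#' observations and the pooled values carry no ties, the p-value comes from
#' the exact null distribution of the Mann-Whitney U statistic; otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used (average ranks for ties). A pooled sample with zero
#' rank variance (all values identical) yields p = 1.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return Two-sided p-value (single numeric), with attributes `statistic`
#'   (the U statistic of `group_a`) and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # 0.1
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop_input("rank-sum test undefined: both groups must be non-empty")
  }
  if (anyNA(group_a) || anyNA(group_b)) {
    stop_input("rank-sum test: missing values must be removed first")
  }
  na <- length(group_a)
  nb <- length(group_b)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L

  if (!has_ties && max(na, nb) <= 8L) {
    p_lo <- pwilcox(u, na, nb)
    p_hi <- pwilcox(u - 1, na, nb, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    n <- na + nb
    mu <- na * nb / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      # all pooled values identical: no evidence either way
      p <- 1
    } else {
      z <- u - mu
      z <- (z - sign(z) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    }
    method <- "normal_approx"
  }
  structure(p, statistic = u, method = method)
}
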