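# Expression-level interrogation of association hits: group tests by region
# mutation status and expression-activity correlation.

#' Compare expression between two sample groups
#'
#' Rank-sum comparison of a protein's expression between, e.g., samples
#' mutated in a region of interest and samples without such mutations.
#'
#' @param expression Named numeric vector of per-sample expression values.
#' @param group_a_samples,group_b_samples Sample identifiers; samples
#'   without an expression value are dropped.
#' @return List: `p` (two-sided rank-sum), `delta_median` (median of group
#'   A minus group B), `n_a`, `n_b`.
#' @export
expression_group_test <- function(expression, group_a_samples,
                                  group_b_samples) {
  if (is.null(names(expression))) {
    stop_input("`expression` must be a named per-sample vector")
  }
  a <- expression[intersect(group_a_samples, names(expression))]
  b <- expression[intersect(group_b_samples, names(expression))]
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop_input("both groups need at least one sample with expression data")
  }
  p <- as.numeric(rank_sum_test(a, b))
  list(p = p, delta_median = median(a) - median(b),
       n_a = length(a), n_b = length(b))
}

#' Pearson correlation between expression and drug activity
#'
#' @param expression,activity Per-sample numeric vectors, matched by name
#'   when both are named, by position otherwise. Pairs with a missing value
#'   are dropped; at least 3 complete pairs are required.
#' @return List: `r` (Pearson coefficient), `p` (two-sided, t-transform on
#'   n-2 degrees of freedom), `n`.
#' @export
expression_activity_correlation <- function(expression, activity) {
  if (!is.null(names(expression)) && !is.null(names(activity))) {
    common <- intersect(names(expression), names(activity))
    expression <- expression[common]
    activity <- activity[common]
  }
  if (length(expression) != length(activity)) {
    stop_input("expression and activity vectors must be matched")
  }
  ok <- !is.na(expression) & !is.na(activity)
  x <- expression[ok]
  y <- activity[ok]
  if (length(x) < 3L) {
    stop_input("need at least 3 paired observations (got %d)", length(x))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_input("correlation undefined: zero variance in one of the vectors")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
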