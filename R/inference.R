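#' Cross-classify matched pairs by outcome
#'
#' Classifies each matched treated-control pair by the pair of binary
#' outcomes: `a` pairs where both members have the event, `b` where only the
#' treated member does, `c` where only the control member does, and `d` where
#' neither does. All paired inference is driven by these four counts; only
#' the discordant counts `b` and `c` carry information about the treatment
#' effect.
#'
#' @param matched a `matched_sample` (see [greedy_match()]).
#' @param Y binary outcome vector indexed by subject.
#' @return an object of class `paired_table`: list with counts `a`, `b`,
#'   `c`, `d` and total `n`.
#' @export
paired_table <- function(matched, Y) {
  stopifnot(inherits(matched, "matched_sample"))
  if (nrow(matched$pairs) == 0L) {
    stop("empty matched sample: no pairs to tabulate")
  }
  yt <- Y[matched$pairs[, "treated"]]
  yc <- Y[matched$pairs[, "control"]]
  new_paired_table(
    a = sum(yt == 1L & yc == 1L),
    b = sum(yt == 1L & yc == 0L),
    c = sum(yt == 0L & yc == 1L),
    d = sum(yt == 0L & yc == 0L)
  )
}

#' Construct a paired 2x2 table from counts
#'
#' @param a,b,c,d non-negative pair counts: both events, treated-only event,
#'   control-only event, no events.
#' @return a `paired_table`.
#' @export
new_paired_table <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(counts >= 0), sum(counts) >= 1)
  structure(
    list(a = a, b = b, c = c, d = d, n = a + b + c + d),
    class = "paired_table"
  )
}

#' @export
print.paired_table <- function(x, ...) {
  cat(sprintf(
    "Paired table (%d pairs): a=%d b=%d c=%d d=%d\n",
    x$n, x$a, x$b, x$c, x$d
  ))
  invisible(x)
}

#' Risk difference in the matched sample
#'
#' The estimated absolute risk reduction: the difference between the event
#' proportion among treated members, \eqn{(a+b)/n}, and among control
#' members, \eqn{(a+c)/n}, i.e. \eqn{(b-c)/n}. The point estimate is the
#' same whether paired or independent-samples methods are used for
#' inference.
#'
#' @param t a `paired_table`.
#' @return the risk difference (numeric scalar in [-1, 1]).
#' @export
risk_difference <- function(t) {
  stopifnot(inherits(t, "paired_table"))
  (t$b - t$c) / t$n
}

#' Independent-samples variance of the risk difference
#'
#' The standard two-independent-proportions variance
#' \eqn{(p_T(1-p_T) + p_C(1-p_C))/N}, treating the \eqn{N} treated and
#' \eqn{N} control members of the matched pairs as independent samples of
#' size \eqn{N} each.
#'
#' @param t a `paired_table`.
#' @return the variance (non-negative scalar).
#' @export
var_independent <- function(t) {
  stopifnot(inherits(t, "paired_table"))
  p_t <- (t$a + t$b) / t$n
  p_c <- (t$a + t$c) / t$n
  (p_t * (1 - p_t) + p_c * (1 - p_c)) / t$n
}

#' Paired-samples variance of the risk difference
#'
#' The variance of a difference in paired proportions,
#' \eqn{((b + c) - (c - b)^2/n)/n^2}, which accounts for the within-pair
#' correlation of outcomes. It differs from the independent-samples variance
#' by exactly \eqn{2(ad - bc)/n^3}, so it is smaller whenever within-pair
#' outcomes are positively associated (\eqn{ad > bc}).
#'
#' @param t a `paired_table`.
#' @return the variance (non-negative scalar).
#' @export
var_paired <- function(t) {
  stopifnot(inherits(t, "paired_table"))
  ((t$b + t$c) - (t$c - t$b)^2 / t$n) / t$n^2
}

#' McNemar's test for paired binary outcomes
#'
#' Tests marginal homogeneity of the event probability between treated and
#' control members of the matched pairs using the discordant counts only:
#' statistic \eqn{(b - c)^2/(b + c)} referred to a chi-squared distribution
#' with one degree of freedom. No continuity correction is applied by
#' default. A table with no discordant pairs gives statistic 0 and p = 1.
#'
#' @param t a `paired_table`.
#' @param correct apply the continuity correction
#'   \eqn{(|b - c| - 1)^2/(b + c)} (off by default).
#' @return list with `statistic` and `p_value`.
#' @export
mcnemar_test <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "paired_table"))
  disc <- t$b + t$c
  if (disc == 0) {
    return(list(statistic = 0, p_value = 1))
  }
  num <- if (correct) (abs(t$b - t$c) - 1)^2 else (t$b - t$c)^2
  stat <- num / disc
  list(statistic = stat, p_value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Pearson chi-squared test on the matched 2x2 table
#'
#' The independent-samples test: the `2n` matched subjects are arranged in a
#' treatment-by-outcome 2x2 table (treated row: \eqn{a+b} events,
#' \eqn{n-a-b} non-events; control row: \eqn{a+c} events, \eqn{n-a-c}
#' non-events) and the ordinary Pearson chi-squared statistic
#' \eqn{\sum (O-E)^2/E} is referred to a chi-squared distribution with one
#' degree of freedom, without continuity correction by default. A table with
#' any zero margin gives statistic 0 and p = 1.
#'
#' @param t a `paired_table`.
#' @param correct apply the Yates continuity correction (off by default).
#' @return list with `statistic` and `p_value`.
#' @export
pearson_test <- function(t, correct = FALSE) {
  stopifnot(inherits(t, "paired_table"))
  n <- t$n
  e_t <- t$a + t$b # events among treated members
  e_c <- t$a + t$c # events among control members
  tab <- matrix(c(e_t, n - e_t, e_c, n - e_c), 2L, 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = 0, p_value = 1))
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- abs(tab - E)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / E)
  list(statistic = stat, p_value = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' Wald confidence interval for the risk difference
#'
#' The interval \eqn{\hat{RD} \pm z \cdot se}, with \eqn{z = 1.96} for the
#' 95 per cent level. The interval is not truncated to [-1, 1].
#'
#' @param rd point estimate of the risk difference.
#' @param se standard error (non-negative).
#' @param level_z normal quantile for the confidence level (default 1.96).
#' @return numeric vector `c(lower, upper)`.
#' @export
wald_ci <- function(rd, se, level_z = 1.96) {
  stopifnot(se >= 0)
  c(lower = rd - level_z * se, upper = rd + level_z * se)
}

#' Full paired and independent-samples inference on a matched sample
#'
#' Computes the risk difference, both variance estimates, both Wald 95 per
#' cent confidence intervals, McNemar's test and the Pearson chi-squared
#' test from one paired table.
#'
#' @param t a `paired_table`.
#' @param level_z normal quantile for the confidence level (default 1.96).
#' @return an object of class `rd_inference`: list with `rd`, `p_T`, `p_C`,
#'   `n_pairs`, `se_independent`, `se_paired`, `ci_independent`,
#'   `ci_paired`, `p_pearson`, `p_mcnemar`.
#' @export
rd_inference <- function(t, level_z = 1.96) {
  stopifnot(inherits(t, "paired_table"))
  rd <- risk_difference(t)
  se_i <- sqrt(var_independent(t))
  se_p <- sqrt(var_paired(t))
  structure(
    list(
      rd = rd,
      p_T = (t$a + t$b) / t$n,
      p_C = (t$a + t$c) / t$n,
      n_pairs = t$n,
      se_independent = se_i,
      se_paired = se_p,
      ci_independent = wald_ci(rd, se_i, level_z),
      ci_paired = wald_ci(rd, se_p, level_z),
      p_pearson = pearson_test(t)$p_value,
      p_mcnemar = mcnemar_test(t)$p_value
    ),
    class = "rd_inference"
  )
}

#' @export
print.rd_inference <- function(x, ...) {
  cat(sprintf(
    "Risk difference %.4f (%d pairs)\n  independent: se %.4f, 95%% CI (%.4f, %.4f), Pearson p %.4f\n  paired:      se %.4f, 95%% CI (%.4f, %.4f), McNemar p %.4f\n",
    x$rd, x$n_pairs,
    x$se_independent, x$ci_independent[1], x$ci_independent[2], x$p_pearson,
    x$se_paired, x$ci_paired[1], x$ci_paired[2], x$p_mcnemar
  ))
  invisible(x)
}
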