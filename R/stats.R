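#' Proportion with its standard error
#'
#' @param successes Number of successes.
#' @param n Number of trials.
#' @return data.frame with `successes`, `n`, `p_hat` and
#'   `se = sqrt(p_hat (1 - p_hat) / n)`.
#' @export
proportionSummary <- function(successes, n) {
  if (any(successes < 0 | successes > n)) stop("need 0 <= successes <= n")
  p <- successes / n
  data.frame(successes = successes, n = n, p_hat = p,
             se = sqrt(p * (1 - p) / n))
}

#' Two-proportion Z-test (pooled variance)
#'
#' Tests the difference of two binomial proportions with the pooled
#' standard error \eqn{\sqrt{\bar p(1-\bar p)(1/n_1 + 1/n_2)}} and a normal
#' reference distribution; no continuity correction by default. On binary
#' data this statistic coincides numerically with the tie-corrected
#' rank-sum (Mann-Whitney) test, which is why figure-legend "U-test"
#' p-values on proportions are reproduced by this function.
#'
#' @param successes1,n1 First sample.
#' @param successes2,n2 Second sample.
#' @param tail `"greater"` (p1 > p2, default), `"less"` or `"two.sided"`.
#' @param correct Apply a continuity correction (default `FALSE`).
#' @return List with `z`, `p`, `p1`, `p2`, `pooled`.
#' @examples
#' twoPropZ(200, 271, 377, 599)$p   # ~ 8.5e-4
#' twoPropZ(54, 199, 7, 53)$p       # ~ 0.018
#' @export
twoPropZ <- function(successes1, n1, successes2, n2,
                     tail = c("greater", "less", "two.sided"),
                     correct = FALSE) {
  tail <- match.arg(tail)
  if (n1 < 1 || n2 < 1) stop("both sample sizes must be >= 1")
  p1 <- successes1 / n1
  p2 <- successes2 / n2
  pp <- (successes1 + successes2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) {
    if (p1 != p2) warning("zero pooled variance with unequal proportions; ",
                          "reporting limiting p-value")
    z <- if (p1 == p2) 0 else sign(p1 - p2) * Inf
  } else {
    d <- p1 - p2
    if (correct) d <- sign(d) * max(0, abs(d) - 0.5 * (1 / n1 + 1 / n2))
    z <- d / se
  }
  p <- switch(tail,
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z),
    two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
  list(z = z, p = min(p, 1), p1 = p1, p2 = p2, pooled = pp)
}

#' Pearson chi-square test on a 2 x k table
#'
#' @param successes Vector of successes per group, or a 2 x k matrix of
#'   counts (rows: success/failure).
#' @param totals Vector of group totals (ignored for matrix input).
#' @return List with `statistic`, `df` (= k - 1) and `p`.
#' @export
chiSquare2xk <- function(successes, totals = NULL) {
  if (is.matrix(successes)) {
    tab <- successes
  } else {
    if (is.null(totals)) stop("'totals' required with vector input")
    tab <- rbind(successes, totals - successes)
  }
  if (any(tab < 0)) stop("counts must be non-negative")
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum test of two samples: exact enumeration when both samples are
#' small (min n <= 8) and untied, tie-corrected normal approximation
#' otherwise (no continuity correction, matching the exact tail closely at
#' moderate n).
#'
#' @param x,y Numeric samples.
#' @param tail `"greater"` (x tends larger, default), `"less"` or
#'   `"two.sided"`.
#' @return List with `u` (number of (x, y) pairs with x > y, ties counted
#'   half) and `p`.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4), tail = "less")$p  # 1/6
#' @export
mannWhitneyU <- function(x, y, tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  alt <- switch(tail, greater = "greater", less = "less",
                two.sided = "two.sided")
  ties <- any(duplicated(c(x, y)))
  exact <- !ties && min(length(x), length(y)) <= 8
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alt, exact = exact,
                       correct = FALSE))
  p <- ht$p.value
  if (is.nan(p))  # zero rank variance: every observation tied
    p <- if (tail == "two.sided") 1 else 0.5
  list(u = unname(ht$statistic), p = p)
}

#' One-sample t-test
#'
#' @param values Numeric sample.
#' @param mu0 Null mean.
#' @param tail `"greater"` (mean > mu0, default), `"less"` or
#'   `"two.sided"`.
#' @return List with `t`, `df` and `p`.
#' @export
oneSampleT <- function(values, mu0 = 0,
                       tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  ht <- stats::t.test(values, mu = mu0, alternative = tail)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}
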