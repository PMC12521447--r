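#' Power of a two-sample t test at given group sizes
#'
#' Exact noncentral-t evaluation: with effect size d, the noncentrality is
#' \eqn{\delta = d \sqrt{n_1 n_2 / (n_1 + n_2)}} on \eqn{n_1 + n_2 - 2}
#' degrees of freedom; power is the probability mass of the noncentral t
#' beyond the (two- or one-tailed) critical value.
#'
#' @param n1,n2 group sizes.
#' @param d standardized mean difference (Cohen's d).
#' @param alpha significance level.
#' @param tails 1 or 2.
#' @return Power in (0, 1).
#' @export
powerAtN <- function(n1, n2, d, alpha = 0.05, tails = 2) {
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tc <- stats::qt(1 - alpha / tails, df)
  pw <- 1 - stats::pt(tc, df, ncp = ncp)
  if (tails == 2) pw <- pw + stats::pt(-tc, df, ncp = ncp)
  pw
}

#' A-priori sample size for a two-sample t test
#'
#' Smallest total sample size (equal allocation by default) whose exact
#' noncentral-t power reaches the target. Equivalent to the standard
#' a-priori computation for independent-samples t tests.
#'
#' @param d standardized effect size (nonzero).
#' @param alpha significance level.
#' @param power target power.
#' @param tails 1 or 2.
#' @param ratio allocation ratio n2/n1.
#' @param nCap search cap on n1.
#' @return list: \code{nTotal}, \code{n1}, \code{n2},
#'   \code{achievedPower}.
#' @examples
#' powerTwoSampleT(d = 0.77)$nTotal  # 56
#' @export
powerTwoSampleT <- function(d, alpha = 0.05, power = 0.80, tails = 2,
                            ratio = 1, nCap = 1e5) {
  if (d == 0) stop("effect size must be nonzero")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must lie in (0, 1)")
  d <- abs(d)
  for (n1 in 2:nCap) {
    n2 <- max(2, round(n1 * ratio))
    pw <- powerAtN(n1, n2, d, alpha, tails)
    if (pw >= power)
      return(list(nTotal = n1 + n2, n1 = n1, n2 = n2, achievedPower = pw))
  }
  stop("target power unreachable within the configured cap")
}
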