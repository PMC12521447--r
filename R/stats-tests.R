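#' Normality screening (Lilliefors-corrected Kolmogorov-Smirnov)
#'
#' One-sample KS test against a normal distribution with estimated mean and
#' SD, using the Lilliefors correction for the estimated parameters
#' (\code{nortest::lillie.test}). Requires n >= 5; constant input is
#' degenerate and flagged via an error.
#'
#' @param x numeric sample.
#' @return list with \code{statistic} (D) and \code{p}.
#' @export
ksNormality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 5) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("constant input: distribution is degenerate")
  t <- nortest::lillie.test(x)
  list(statistic = unname(t$statistic), p = unname(t$p.value))
}

#' Partial eta squared from an F statistic
#'
#' \eqn{\eta_p^2 = F df_1 / (F df_1 + df_2)}, the proportion of
#' effect-plus-error variance attributable to the effect.
#'
#' @param f F statistic.
#' @param df1,df2 numerator and denominator degrees of freedom.
#' @return Numeric in [0, 1].
#' @examples
#' partialEtaSq(8.05, 1, 52)  # 0.13 at 2 dp
#' @export
partialEtaSq <- function(f, df1, df2) {
  f * df1 / (f * df1 + df2)
}

#' Confidence interval for partial eta squared
#'
#' One-sided 95\% construction (lower bound from the noncentral-F
#' distribution, upper bound fixed at 1), the convention under which
#' effect-size intervals for F tests are reported with an upper limit
#' printed as 1.00. The lower bound solves
#' \code{pf(F, df1, df2, ncp) = 1 - level} for the noncentrality parameter
#' and maps it to eta squared via \code{ncp / (ncp + df1 + df2 + 1)}.
#'
#' @param f,df1,df2 observed F and its degrees of freedom.
#' @param level one-sided confidence level (default 0.95).
#' @return c(lower, upper); upper is 1.
#' @export
partialEtaSqCi <- function(f, df1, df2, level = 0.95) {
  g <- function(ncp) stats::pf(f, df1, df2, ncp = ncp) - level
  lower <- if (g(0) <= 0) 0 else {
    up <- 1
    while (g(up) > 0) up <- up * 2
    ncp <- stats::uniroot(g, c(0, up))$root
    ncp / (ncp + df1 + df2 + 1)
  }
  c(lower = lower, upper = 1)
}

#' One-way analysis of variance with effect size
#'
#' Classical between/within decomposition via \code{stats::aov}, augmented
#' with partial eta squared, its one-sided 95\% CI, group descriptives and
#' - for two groups - the pooled-variance mean difference with its 95\% t
#' confidence interval (equivalent to the pooled two-sample t test;
#' F = t^2).
#'
#' @param values numeric outcome.
#' @param groups group labels (>= 2 groups, each n >= 2).
#' @return list of class \code{anovaResult}: \code{F}, \code{df1},
#'   \code{df2}, \code{p}, \code{partialEtaSq}, \code{etaCi},
#'   \code{groupMeans}, \code{groupSds}, \code{groupNs}, and for two groups
#'   \code{meanDiff}, \code{meanDiffCi}.
#' @examples
#' r <- oneWayAnova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' r$F  # 13.5
#' @export
oneWayAnova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  f <- tab[1, "F value"]
  df1 <- tab[1, "Df"]; df2 <- tab[2, "Df"]
  out <- list(F = f, df1 = df1, df2 = df2, p = tab[1, "Pr(>F)"],
              partialEtaSq = partialEtaSq(f, df1, df2),
              etaCi = partialEtaSqCi(f, df1, df2),
              groupMeans = tapply(values, groups, mean),
              groupSds = tapply(values, groups, stats::sd),
              groupNs = as.numeric(table(groups)))
  if (nlevels(groups) == 2) {
    n <- out$groupNs
    sp <- sqrt(((n[1] - 1) * out$groupSds[1]^2 +
                  (n[2] - 1) * out$groupSds[2]^2) / (sum(n) - 2))
    se <- sp * sqrt(1 / n[1] + 1 / n[2])
    diff <- unname(out$groupMeans[1] - out$groupMeans[2])
    tc <- stats::qt(0.975, sum(n) - 2)
    out$meanDiff <- diff
    out$meanDiffCi <- c(diff - tc * se, diff + tc * se)
    out$cohenD <- diff / sp
  }
  class(out) <- "anovaResult"
  out
}

#' @export
print.anovaResult <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.2f, p = %.4g, partial eta^2 = %.3f [%.2f, %.2f]\n",
              x$df1, x$df2, x$F, x$p, x$partialEtaSq,
              x$etaCi[1], x$etaCi[2]))
  if (!is.null(x$meanDiff))
    cat(sprintf("mean difference = %.4g [%.4g, %.4g], d = %.2f\n",
                x$meanDiff, x$meanDiffCi[1], x$meanDiffCi[2], x$cohenD))
  invisible(x)
}

#' Independent-samples t test with Cohen's d
#'
#' Pooled-variance t test by default (so that F = t^2 against the two-group
#' ANOVA); Welch's correction available via \code{pooled = FALSE}. Cohen's
#' d always uses the pooled SD.
#'
#' @param x,y numeric samples (each n >= 2).
#' @param pooled pooled-variance (default) or Welch.
#' @return list: \code{t}, \code{df}, \code{p}, \code{d}, \code{meanDiff},
#'   \code{ci} (95\%).
#' @export
twoSampleT <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) stop("zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = (mean(x) - mean(y)) / sqrt(sp2),
       meanDiff = mean(x) - mean(y),
       ci = as.numeric(tt$conf.int))
}

#' Wilcoxon rank-sum test
#'
#' W statistic with the exact distribution for small untied samples (both
#' n <= 25, no ties) and the normal approximation with tie correction
#' otherwise.
#'
#' @param x,y numeric samples.
#' @return list: \code{W}, \code{p}, \code{method}.
#' @export
wilcoxonRankSum <- function(x, y) {
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 25 && length(y) <= 25 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = FALSE))
  list(W = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Contingency-table tests
#'
#' Pearson chi-square without continuity correction for r x c tables
#' (df = (r-1)(c-1)), or Fisher's exact test (2 x 2, two-sided p by summing
#' hypergeometric probabilities not exceeding that of the observed table).
#'
#' @param counts matrix of non-negative counts.
#' @param kind "chi_square" or "fisher".
#' @return list: \code{statistic} (chi-square; NA for Fisher), \code{df}
#'   (chi-square only), \code{p}.
#' @examples
#' phase <- matrix(c(8, 4, 2, 6, 4, 1, 6, 6, 3), nrow = 3, byrow = TRUE)
#' contingencyTest(phase, "chi_square")  # chi2(4) = 1.28
#' @export
contingencyTest <- function(counts, kind = c("chi_square", "fisher")) {
  kind <- match.arg(kind)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (kind == "chi_square") {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(statistic = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value)
  } else {
    if (!all(dim(counts) == c(2, 2)))
      stop("Fisher's exact test is implemented for 2 x 2 tables")
    ft <- stats::fisher.test(counts)
    list(statistic = NA_real_, df = NA_real_, p = ft$p.value)
  }
}

#' Normal sample with exact moments
#'
#' Deterministic standard-normal-shaped sample rescaled to have exactly the
#' requested mean and (n-1 denominator) SD. Used to reconstruct analyses
#' from printed group summaries: any statistic that depends on the data
#' only through the first two moments (t tests, ANOVA, pooled CIs) is then
#' reproduced exactly.
#'
#' @param n sample size.
#' @param mean,sd target moments.
#' @return numeric vector of length n.
#' @examples
#' x <- momentNormalSample(30, -0.080, 0.033)
#' c(mean(x), sd(x))
#' @export
momentNormalSample <- function(n, mean = 0, sd = 1) {
  z <- stats::qnorm(stats::ppoints(n))
  z <- (z - mean(z)) / stats::sd(z)
  mean + sd * z
}
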