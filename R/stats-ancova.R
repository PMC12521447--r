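#' Type II analysis of covariance
#'
#' Linear model of the outcome on group plus covariates, with per-term
#' Type II sums of squares (each term's SS is the residual-SS increase when
#' that term alone is removed while all others are retained), F tests
#' against the full-model residual mean square, partial eta squared per
#' term, estimated marginal means per group at the covariate sample means,
#' variance inflation factors, and model R-squared. Type II SS and VIF are
#' computed via \pkg{car}, EMMs via \pkg{emmeans}.
#'
#' @param data data.frame holding the columns named below.
#' @param outcome outcome column name.
#' @param group grouping column name (coerced to factor).
#' @param covariates character vector of covariate column names.
#' @return list of class \code{ancovaResult}: \code{terms} (data.frame with
#'   term, SS, df, F, p, partialEtaSq), \code{emm} (data.frame: group,
#'   emmean, se), \code{vif} (named), \code{r2}, \code{r2adj},
#'   \code{residDf}.
#' @examples
#' d <- data.frame(y = rnorm(40), g = rep(c("a", "b"), 20), x = rnorm(40))
#' ancovaType2(d, "y", "g", "x")$terms
#' @export
ancovaType2 <- function(data, outcome, group,
                        covariates = c("age", "bdi_cognitive",
                                       "bdi_somatic_affective")) {
  cols <- c(outcome, group, covariates)
  missingCols <- setdiff(cols, names(data))
  if (length(missingCols))
    stop("missing columns: ", paste(missingCols, collapse = ", "))
  d <- data[, cols]
  d[[group]] <- factor(d[[group]])
  if (nrow(d) <= length(covariates) + 2)
    stop("too few observations for the requested model")
  form <- stats::as.formula(paste(outcome, "~",
                                  paste(c(group, covariates),
                                        collapse = " + ")))
  fit <- stats::lm(form, data = d)
  if (fit$rank < length(covariates) + nlevels(d[[group]])) {
    ali <- names(which(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear terms: ",
         paste(ali, collapse = ", "))
  }
  a2 <- car::Anova(fit, type = 2)
  ssRes <- a2["Residuals", "Sum Sq"]
  dfRes <- a2["Residuals", "Df"]
  terms <- rownames(a2)[rownames(a2) != "Residuals"]
  tab <- data.frame(
    term = terms,
    SS = a2[terms, "Sum Sq"],
    df = a2[terms, "Df"],
    F = a2[terms, "F value"],
    p = a2[terms, "Pr(>F)"],
    partialEtaSq = a2[terms, "Sum Sq"] / (a2[terms, "Sum Sq"] + ssRes),
    row.names = NULL, stringsAsFactors = FALSE
  )
  em <- as.data.frame(emmeans::emmeans(fit, specs = group))
  emm <- data.frame(group = em[[1]], emmean = em$emmean, se = em$SE,
                    stringsAsFactors = FALSE)
  vifs <- car::vif(fit)
  if (is.matrix(vifs)) vifs <- stats::setNames(vifs[, 1], rownames(vifs))
  sm <- summary(fit)
  out <- list(terms = tab, emm = emm, vif = vifs,
              r2 = sm$r.squared, r2adj = sm$adj.r.squared,
              residDf = dfRes, fit = fit)
  class(out) <- "ancovaResult"
  out
}

#' @export
print.ancovaResult <- function(x, ...) {
  cat("Type II ANCOVA\n")
  tab <- x$terms
  tab$partialEtaSq <- round(tab$partialEtaSq, 3)
  print(tab, digits = 4)
  cat(sprintf("R^2 = %.3f, adjusted R^2 = %.3f\n", x$r2, x$r2adj))
  cat("EMMs:\n"); print(x$emm, digits = 4)
  invisible(x)
}
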