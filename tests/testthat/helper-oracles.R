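# Independent oracles used to cross-check the implementation. These are
# deliberately naive (normal equations, exhaustive enumeration, model
# refits) and share no code with the package internals.

# OLS slope/intercept by explicit normal equations
oracleOls <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# Type II sum of squares for every term by full-vs-reduced refits on the
# model matrix columns
oracleType2 <- function(formula, data) {
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(formula, mf)
  asgn <- attr(X, "assign")
  rssOf <- function(cols) {
    fit <- lm.fit(X[, cols, drop = FALSE], y)
    sum(fit$residuals^2)
  }
  rssFull <- rssOf(seq_len(ncol(X)))
  terms <- setdiff(unique(asgn), 0)
  ss <- vapply(terms, function(t) rssOf(which(asgn != t)) - rssFull,
               numeric(1))
  names(ss) <- attr(terms(mf), "term.labels")
  list(ss = ss, rssFull = rssFull,
       dfResid = nrow(X) - ncol(X))
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration over all tables with the observed margins
oracleFisher2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  pObs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Pearson chi-square by explicit cell contributions
oracleChisq <- function(tab) {
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp)^2 / exp)
}
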