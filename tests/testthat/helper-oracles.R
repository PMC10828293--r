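# Independent oracles used to cross-check the package's model fits.

# Normal-equations OLS: beta = (X'X)^-1 X'y, se from sigma^2 (X'X)^-1.
ols_oracle <- function(X, y) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / (nrow(X) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(XtX_inv) * sigma2))
}

# Exhaustive Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) m / j,
# capped at 1, in input order.  Deliberately written as a double loop.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, ps[j] * m / j)
    q_sorted[i] <- min(best, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Small complete analysis dataset for battery-level tests: cohort covariates,
# LTL exposure columns and z-scale outcomes drawn from a config.
make_analysis_data <- function(config, panels = "gws_codd") {
  gen <- generate_cohort(config)
  ph <- draw_phenotypes_z(gen$cohort, gen$truth, config)
  ltl <- build_ltl_measures(gen$truth$ltl, gen$dosages, gen$weights,
                            gen$cohort, panels = panels)
  d <- cbind(gen$cohort, ltl[-1], ph[-1])
  list(data = d, gen = gen)
}
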