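# Internal numerical helpers shared by the generator and the exposure modules.

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and variance of N(mean, sd^2) truncated to [lower, upper].
#' Used by the cohort generator so that covariate z-scores built from truncated
#' draws have exact population mean 0 and variance 1, which in turn makes the
#' planted-outcome variance bookkeeping exact.
#'
#' @param mean,sd Parameters of the parent normal.
#' @param lower,upper Truncation bounds (may be -Inf / Inf).
#' @return List with elements `mean` and `var`.
#' @keywords internal
truncnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  phi_a <- stats::dnorm(a)
  phi_b <- stats::dnorm(b)
  m <- mean + sd * (phi_a - phi_b) / Z
  aphja <- if (is.finite(a)) a * phi_a else 0
  bphjb <- if (is.finite(b)) b * phi_b else 0
  v <- sd^2 * (1 + (aphja - bphjb) / Z - ((phi_a - phi_b) / Z)^2)
  list(mean = m, var = v)
}

# Exact inverse-CDF sampler for the truncated normal (vectorized, no rejection).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  pa <- stats::pnorm(lower, mean, sd)
  pb <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pa, pb), mean, sd)
}

# Dirichlet draws via normalized gammas; rows are simplex points.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n), rate = 1),
              nrow = n, ncol = k)
  g / rowSums(g)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Solve for parent normal parameters such that the truncated distribution
# has the requested mean and SD (fixed-point iteration; converges in a few
# steps for the mild truncations used here).
match_truncnorm <- function(mean_target, sd_target, lower, upper,
                            iter = 60) {
  mu <- mean_target
  sigma <- sd_target
  for (i in seq_len(iter)) {
    mom <- truncnorm_moments(mu, sigma, lower, upper)
    mu <- mu + (mean_target - mom$mean)
    sigma <- sigma * sd_target / sqrt(mom$var)
  }
  list(mean = mu, sd = sigma)
}
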