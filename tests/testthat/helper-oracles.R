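# Independent oracles used to cross-check the package implementations.
# Each is written from the definition, not from the code path it checks.

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# assignments of the pooled values to group A.
enum_wilcox_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  idx <- utils::combn(length(pooled), n_a)
  u_all <- apply(idx, 2L, function(i) sum(r[i]) - n_a * (n_a + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Cox partial log-likelihood for tie-free data with a single covariate.
cox_partial_loglik <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  eta <- beta * x
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      at_risk <- time >= time[i]
      ll <- ll + eta[i] - log(sum(exp(eta[at_risk])))
    }
  }
  ll
}

# Multi-covariate version (X a matrix), used to evaluate fitted models.
cox_partial_loglik_multi <- function(beta, time, event, X) {
  eta <- as.numeric(X %*% beta)
  ll <- 0
  for (i in seq_along(time)) {
    if (event[i] == 1) {
      ll <- ll + eta[i] - log(sum(exp(eta[time >= time[i]])))
    }
  }
  ll
}

# One-covariate maximizer by golden-section search on the coded likelihood.
cox_oracle_beta <- function(time, event, x) {
  stats::optimize(function(b) cox_partial_loglik(b, time, event, x),
                  interval = c(-20, 20), maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Bernoulli log-likelihood and a gradient-free maximizer for logistic
# regression with intercept.
logistic_loglik <- function(beta, y, X) {
  eta <- as.numeric(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

logistic_oracle_beta <- function(y, X) {
  stats::optim(rep(0, ncol(X)), function(b) -logistic_loglik(b, y, X),
               method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))$par
}

# Clopper-Pearson endpoints by root-finding on the exact binomial tails
# (the smallest/largest p0 not rejected at alpha/2 each side).
cp_oracle <- function(x, n, confidence = 0.95) {
  alpha <- 1 - confidence
  lower <- if (x == 0) 0 else
    stats::uniroot(function(p0) stats::pbinom(x - 1, n, p0,
                                              lower.tail = FALSE) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (x == n) 1 else
    stats::uniroot(function(p0) stats::pbinom(x, n, p0) - alpha / 2,
                   c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower = lower, upper = upper)
}

# Small tie-free survival dataset generator for oracle comparisons.
random_survival_toy <- function(n, seed) {
  withr::with_seed(seed, {
    repeat {
      d <- data.frame(time = round(stats::rexp(n, 0.3), 6),
                      event = stats::rbinom(n, 1, 0.8),
                      x = stats::rnorm(n))
      if (sum(d$event) >= 2 && !anyDuplicated(d$time)) return(d)
    }
  })
}

# Minimal clinical table generator for model tests.
toy_clinical <- function(n, seed = 1) {
  withr::with_seed(seed, data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    os_time = stats::rexp(n, 0.1),
    os_event = stats::rbinom(n, 1, 0.75),
    pfs_time = stats::rexp(n, 0.2),
    pfs_event = stats::rbinom(n, 1, 0.85),
    response = stats::rbinom(n, 1, 0.3),
    x = stats::rnorm(n),
    z = stats::rnorm(n),
    stringsAsFactors = FALSE
  ))
}
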