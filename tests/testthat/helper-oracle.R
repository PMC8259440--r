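# Independent brute-force integration oracle used to check the package's
# Gauss-Hermite path: adaptive quadrature over the covariate sum
# s ~ Normal(0, k). Kept deliberately separate from the implementation.
oracle_expect <- function(f, k) {
  stats::integrate(function(s) f(s) * stats::dnorm(s, 0, sqrt(k)),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

oracle_marginal_risk <- function(x, beta_xy, beta_cy, i2 = 0, k = 3) {
  oracle_expect(function(s) plogis(i2 + beta_xy * x + beta_cy * s), k)
}

oracle_effects <- function(beta_xy, lambda_cx, beta_cy, i2 = 0, i3 = 0, k = 3) {
  m1 <- oracle_marginal_risk(1, beta_xy, beta_cy, i2, k)
  m0 <- oracle_marginal_risk(0, beta_xy, beta_cy, i2, k)
  prx <- function(s, x) {
    p <- plogis(i3 + lambda_cx * s)
    if (x == 1) p else 1 - p
  }
  ey <- function(x) {
    oracle_expect(function(s) plogis(i2 + beta_xy * x + beta_cy * s) * prx(s, x), k) /
      oracle_expect(function(s) prx(s, x), k)
  }
  list(marginal = qlogis(m1) - qlogis(m0),
       conditional = beta_xy,
       unadjusted = qlogis(ey(1)) - qlogis(ey(0)))
}

# A hand-built 2x2 cohort from cell counts (y,x): n11, n01, n10, n00,
# with no covariates.
cohort_2x2 <- function(n11, n01, n10, n00) {
  y <- c(rep(1, n11), rep(0, n01), rep(1, n10), rep(0, n00))
  x <- c(rep(1, n11 + n01), rep(0, n10 + n00))
  cohort(matrix(numeric(0), nrow = length(y), ncol = 0), x, y)
}

# Replication means of the three estimators under one condition, using the
# exported user-level fitting functions.
replicate_triplets <- function(beta_xy, lambda_cx, beta_cy, n, reps,
                               seed_base) {
  out <- matrix(NA_real_, reps, 3,
                dimnames = list(NULL, c("beta1", "beta1_prime", "beta1_star")))
  for (r in seq_len(reps)) {
    ch <- generate_cohort(generation_params(n, beta_xy, lambda_cx, beta_cy,
                                            seed = seed_base + r))
    tri <- estimate_effects(ch)
    if (tri$converged) {
      out[r, ] <- c(tri$beta1, tri$beta1_prime, tri$beta1_star)
    }
  }
  out[stats::complete.cases(out), , drop = FALSE]
}
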