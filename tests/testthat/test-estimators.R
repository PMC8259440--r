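test_that("univariable fit recovers the closed-form 2x2 log odds ratio", {
  ch <- cohort_2x2(30, 20, 20, 30)
  fit <- fit_univariable(ch)
  expect_equal(fit$exposure_coefficient, log(30 * 30 / (20 * 20)),
               tolerance = 1e-6)
  expect_true(fit$converged)
  expect_true(fit$ci_low <= fit$exposure_coefficient &&
                fit$exposure_coefficient <= fit$ci_high)
})

test_that("degenerate designs are rejected with a clear message", {
  ch_all1 <- cohort(matrix(rnorm(20), 20, 1), rep(1, 20),
                    rbinom(20, 1, 0.5))
  expect_error(fit_univariable(ch_all1), "exposure is constant")
  ch_y0 <- cohort(matrix(rnorm(20), 20, 1), rbinom(20, 1, 0.5), rep(0, 20))
  expect_error(fit_univariable(ch_y0), "outcome is constant")
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  set.seed(21)
  C <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("c1", "c2")))
  C <- cbind(C, c3 = C[, "c1"])
  ch <- cohort(C, rbinom(100, 1, 0.5), rbinom(100, 1, 0.5))
  expect_error(fit_multivariable(ch), "c3")
  expect_error(estimate_propensity(ch), "c3")
})

test_that("multivariable fit with zero covariates reduces to univariable", {
  ch <- cohort_2x2(30, 20, 20, 30)
  uni <- fit_univariable(ch)
  mv <- fit_multivariable(ch)
  expect_identical(mv$model_kind, "multivariable")
  expect_equal(mv$exposure_coefficient, uni$exposure_coefficient)
  expect_equal(mv$standard_error, uni$standard_error)
})

test_that("weight formulas follow the propensity-score definitions", {
  # exposed at PS 0.5, unstabilized -> 1/0.5 = 2; same unexposed
  set.seed(31)
  ch <- generate_cohort(generation_params(2000, 0, 0.92, 0, seed = 31L))
  pw_raw <- estimate_propensity(ch, stabilized = FALSE)
  expect_equal(pw_raw$weights,
               ifelse(ch$exposure == 1, 1 / pw_raw$propensity,
                      1 / (1 - pw_raw$propensity)))
  pw_st <- estimate_propensity(ch, stabilized = TRUE)
  p <- mean(ch$exposure)
  expect_equal(pw_st$marginal_exposure_prob, p)
  expect_equal(pw_st$weights,
               ifelse(ch$exposure == 1, p / pw_st$propensity,
                      (1 - p) / (1 - pw_st$propensity)))
  # spot values: exposed subject at PS 0.8 with p = 0.4 weighs 0.4/0.8 = 0.5
  expect_equal(0.4 / 0.8, 0.5)
  # stabilized weights sum to about n
  expect_lt(abs(sum(pw_st$weights) - length(ch$exposure)),
            0.01 * length(ch$exposure))
})

test_that("propensity is flat when covariates do not affect exposure", {
  # true PS is the constant exposure prevalence; the fitted PS spreads only
  # by the sampling noise of the propensity coefficients (O(1/sqrt(n)))
  ch <- generate_cohort(generation_params(50000, 0.92, 0, 0.92, seed = 32L))
  pw <- estimate_propensity(ch)
  dev <- abs(pw$propensity - mean(ch$exposure))
  expect_lt(sd(pw$propensity), 0.01)
  expect_lt(quantile(dev, 0.99), 0.02)
  expect_lt(max(dev), 0.05)
})

test_that("equal weights leave the IPW estimate at the univariable value", {
  ch <- generate_cohort(generation_params(800, 0.92, 0.92, 0.92, seed = 33L))
  uni <- fit_univariable(ch)
  ipw <- fit_ipw(ch, weights = rep(2, 800))
  expect_equal(ipw$exposure_coefficient, uni$exposure_coefficient,
               tolerance = 1e-8)
})

test_that("stabilized and unstabilized weights give identical IPW estimates", {
  for (seed in c(41L, 42L, 43L)) {
    ch <- generate_cohort(generation_params(600, 0.38, 0.92, -0.92,
                                            seed = seed))
    b_raw <- fit_ipw(ch, estimate_propensity(ch, stabilized = FALSE))
    b_st <- fit_ipw(ch, estimate_propensity(ch, stabilized = TRUE))
    expect_equal(b_st$exposure_coefficient, b_raw$exposure_coefficient,
                 tolerance = 1e-6)
  }
})

test_that("non-positive weights are rejected", {
  ch <- generate_cohort(generation_params(100, 0.92, 0, 0, seed = 44L))
  expect_error(fit_ipw(ch, weights = rep(-1, 100)), "positive")
  expect_error(fit_ipw(ch, weights = rep(1, 50)), "aligned")
})

test_that("estimators are consistent for their theoretical limits", {
  # single large cohort, each estimate within 3 SEs of its limit
  ch <- generate_cohort(generation_params(50000, 0.92, 0.92, 0, seed = 51L))
  uni <- fit_univariable(ch)
  # with beta_cy = 0 the unadjusted limit is beta_xy itself
  expect_lt(abs(uni$exposure_coefficient - 0.92), 3 * uni$standard_error)

  ch2 <- generate_cohort(generation_params(50000, 0.92, 0.92, 0.92, seed = 52L))
  mv <- fit_multivariable(ch2)
  expect_lt(abs(mv$exposure_coefficient - 0.92), 3 * mv$standard_error)
  ipw <- fit_ipw(ch2)
  # frozen quadrature oracle: marginal logOR at all effects 0.92 = 0.6349203
  expect_lt(abs(ipw$exposure_coefficient - 0.6349203),
            3 * ipw$standard_error)
})

test_that("G-computation targets the marginal effect", {
  # no covariate-outcome effect: marginal and conditional coincide
  ch <- generate_cohort(generation_params(50000, 0.92, 0.92, 0, seed = 61L))
  gc <- fit_gcomputation(ch)
  mv <- fit_multivariable(ch)
  expect_lt(abs(gc$exposure_coefficient - mv$exposure_coefficient), 0.05)

  # with no covariates it equals the unadjusted estimate exactly
  ch22 <- cohort_2x2(30, 20, 20, 30)
  expect_equal(fit_gcomputation(ch22)$exposure_coefficient,
               fit_univariable(ch22)$exposure_coefficient, tolerance = 1e-8)

  # at large n it agrees with IPW: both estimate the marginal logOR
  chL <- generate_cohort(generation_params(100000, 0.92, 0.92, 0.92, seed = 62L))
  gcL <- fit_gcomputation(chL)
  ipwL <- fit_ipw(chL)
  expect_lt(abs(gcL$exposure_coefficient - ipwL$exposure_coefficient), 0.05)
  expect_lt(abs(gcL$exposure_coefficient - 0.6349203), 0.05)
})

test_that("identity-link fits are collapsible: multivariable equals IPW", {
  # continuous outcome, linear regression: regression adjustment and IPW
  # estimate the same quantity, unlike the logistic case
  set.seed(71)
  n <- 100000
  C <- matrix(rnorm(3 * n), n, 3)
  s <- rowSums(C)
  x <- rbinom(n, 1, plogis(0.92 * s))
  y <- 0.92 * x + 0.92 * s + rnorm(n)
  ch <- cohort(C, x, y, outcome_type = "continuous")
  mv <- fit_multivariable(ch)
  ipw <- fit_ipw(ch)
  expect_lt(abs(mv$exposure_coefficient - ipw$exposure_coefficient), 0.05)
  expect_lt(abs(mv$exposure_coefficient - 0.92), 0.05)
})

test_that("conditional estimates sit farther from the null than marginal", {
  # attenuation of the marginal effect: with an outcome-associated covariate
  # the multivariable mean exceeds the IPW mean for positive exposure effects
  tri <- replicate_triplets(0.92, 0.92, 0.92, n = 300, reps = 200,
                            seed_base = 7000L)
  expect_gt(mean(tri[, "beta1_prime"]), mean(tri[, "beta1_star"]))
})

test_that("the fast replication path matches the user-level fits", {
  ch <- generate_cohort(generation_params(400, 0.38, -0.92, 0.92, seed = 81L))
  tri <- estimate_effects(ch)
  fast <- noncollapse:::.triplet_fast(ch$covariates, ch$exposure, ch$outcome)
  expect_equal(unname(fast[["beta1"]]), tri$beta1, tolerance = 1e-8)
  expect_equal(unname(fast[["beta1_prime"]]), tri$beta1_prime, tolerance = 1e-8)
  expect_equal(unname(fast[["beta1_star"]]), tri$beta1_star, tolerance = 1e-8)
})
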