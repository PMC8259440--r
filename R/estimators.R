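#' @keywords internal
new_effect_fit <- function(model_kind, exposure_coefficient, intercept,
                           covariate_coefficients, standard_error,
                           ci_low, ci_high, converged, n_used,
                           glm_fit = NULL, note = NULL) {
  structure(list(model_kind = model_kind,
                 exposure_coefficient = unname(exposure_coefficient),
                 intercept = unname(intercept),
                 covariate_coefficients = covariate_coefficients,
                 standard_error = unname(standard_error),
                 ci_low = unname(ci_low), ci_high = unname(ci_high),
                 converged = converged, n_used = n_used,
                 glm_fit = glm_fit, note = note),
            class = "effect_fit")
}

#' @export
print.effect_fit <- function(x, ...) {
  cat(sprintf("%s exposure effect: %.4f (SE %s, 95%% CI %.4f to %.4f), n = %d\n",
              x$model_kind, x$exposure_coefficient,
              if (is.na(x$standard_error)) "-" else sprintf("%.4f", x$standard_error),
              x$ci_low, x$ci_high, x$n_used))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly",
                        if (!is.null(x$note)) paste0(" (", x$note, ")"), "\n")
  invisible(x)
}

# Separation heuristic: fitted probabilities numerically at 0/1.
.separated <- function(fit) {
  if (stats::family(fit)$family == "gaussian") return(FALSE)
  mu <- stats::fitted(fit)
  any(mu < 1e-8 | mu > 1 - 1e-8)
}

.check_not_constant <- function(v, what) {
  if (length(unique(v)) < 2) {
    stop(what, " is constant (all values ", v[1],
         "); the exposure effect is not estimable")
  }
}

.cohort_family <- function(cohort) {
  if (cohort$outcome_type == "binary") stats::binomial() else stats::gaussian()
}

.check_full_rank <- function(C, context) {
  if (ncol(C) == 0) return(invisible(NULL))
  X <- cbind(`(Intercept)` = 1, C)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop(context, ": design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  invisible(NULL)
}

.fit_to_result <- function(fit, model_kind, n, covariate_names = character(0),
                           se_from = c("model", "sandwich", "none")) {
  se_from <- match.arg(se_from)
  cf <- stats::coef(fit)
  beta <- cf[["x"]]
  se <- switch(se_from,
    model = sqrt(diag(stats::vcov(fit)))[["x"]],
    sandwich = sqrt(diag(sandwich::vcovHC(fit, type = "HC0")))[["x"]],
    none = NA_real_)
  sep <- .separated(fit)
  conv <- isTRUE(fit$converged) && !sep && is.finite(beta)
  new_effect_fit(model_kind,
                 exposure_coefficient = beta,
                 intercept = cf[["(Intercept)"]],
                 covariate_coefficients = cf[covariate_names],
                 standard_error = se,
                 ci_low = beta - stats::qnorm(0.975) * se,
                 ci_high = beta + stats::qnorm(0.975) * se,
                 converged = conv, n_used = n, glm_fit = fit,
                 note = if (sep) "perfect or quasi-perfect separation detected" else NULL)
}

#' Unadjusted (univariable) exposure effect
#'
#' Maximum-likelihood logistic regression of the outcome on the exposure
#' alone. The exposure coefficient is the unadjusted log odds ratio, the
#' quantity conventionally compared against the multivariable-adjusted
#' coefficient in the change-in-estimate criterion.
#'
#' @param cohort A [cohort()].
#' @return An `effect_fit` with `model_kind = "univariable"`.
#' @examples
#' ch <- generate_cohort(generation_params(500, 0.92, 0.92, 0.92, seed = 1))
#' fit_univariable(ch)
#' @export
fit_univariable <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  .check_not_constant(cohort$exposure, "exposure")
  .check_not_constant(cohort$outcome, "outcome")
  d <- data.frame(y = cohort$outcome, x = cohort$exposure)
  fit <- stats::glm(y ~ x, family = .cohort_family(cohort), data = d)
  .fit_to_result(fit, "univariable", nrow(d))
}

#' Multivariable confounder-adjusted exposure effect
#'
#' Maximum-likelihood logistic regression of the outcome on the exposure and
#' all covariates. The exposure coefficient is the conditional
#' (within-stratum) adjusted log odds ratio. With zero covariate columns the
#' fit reduces exactly to [fit_univariable()].
#'
#' @param cohort A [cohort()].
#' @return An `effect_fit` with `model_kind = "multivariable"` carrying the
#'   covariate coefficients.
#' @export
fit_multivariable <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  .check_not_constant(cohort$exposure, "exposure")
  .check_not_constant(cohort$outcome, "outcome")
  C <- cohort$covariates
  if (ncol(C) == 0) {
    out <- fit_univariable(cohort)
    out$model_kind <- "multivariable"
    return(out)
  }
  .check_full_rank(cbind(x = cohort$exposure, C), "fit_multivariable")
  d <- data.frame(y = cohort$outcome, x = cohort$exposure, C)
  fml <- stats::reformulate(c("x", colnames(C)), response = "y")
  fit <- stats::glm(fml, family = .cohort_family(cohort), data = d)
  .fit_to_result(fit, "multivariable", nrow(d), covariate_names = colnames(C))
}

#' Propensity scores and inverse-probability weights
#'
#' Fits the propensity model — a logistic regression of exposure on the
#' covariates — and derives per-subject weights. Unstabilized weights are
#' `1/PS` for exposed and `1/(1 - PS)` for unexposed subjects; stabilized
#' weights multiply these by the marginal exposure probability `p`
#' (the sample prevalence): `p/PS` and `(1 - p)/(1 - PS)`. Stabilized
#' weights are the default because raw weights can make the weighted model
#' unstable when propensity scores approach 0 or 1.
#'
#' @param cohort A [cohort()].
#' @param stabilized Logical, default `TRUE`.
#' @return An object of class `propensity_weights` with elements
#'   `propensity`, `weights`, `stabilized`, `marginal_exposure_prob`, and
#'   `flagged` (indices of subjects whose propensity score is numerically
#'   0 or 1).
#' @export
estimate_propensity <- function(cohort, stabilized = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  .check_not_constant(cohort$exposure, "exposure")
  C <- cohort$covariates
  .check_full_rank(C, "estimate_propensity")
  d <- data.frame(x = cohort$exposure)
  if (ncol(C) > 0) {
    d <- cbind(d, C)
    fml <- stats::reformulate(colnames(C), response = "x")
  } else {
    fml <- x ~ 1
  }
  fit <- stats::glm(fml, family = stats::binomial(), data = d)
  ps <- as.numeric(stats::fitted(fit))
  flagged <- which(ps < 1e-10 | ps > 1 - 1e-10)
  if (length(flagged) > 0) {
    warning("propensity score numerically at 0 or 1 for ", length(flagged),
            " subject(s); IPW estimates may be unstable")
  }
  p <- mean(cohort$exposure)
  x <- cohort$exposure
  w <- ifelse(x == 1, 1 / ps, 1 / (1 - ps))
  if (stabilized) w <- w * ifelse(x == 1, p, 1 - p)
  structure(list(propensity = ps, weights = w, stabilized = stabilized,
                 marginal_exposure_prob = p, flagged = flagged,
                 ps_fit = fit),
            class = "propensity_weights")
}

#' @export
print.propensity_weights <- function(x, ...) {
  cat(sprintf("%s IPW weights for %d subjects (p = %.3f)\n",
              if (x$stabilized) "Stabilized" else "Unstabilized",
              length(x$weights), x$marginal_exposure_prob))
  cat(sprintf("  PS range [%.4f, %.4f]; weight sum %.2f\n",
              min(x$propensity), max(x$propensity), sum(x$weights)))
  if (length(x$flagged)) cat("  ", length(x$flagged), "subject(s) flagged at PS 0/1\n")
  invisible(x)
}

#' IPW (marginal) confounder-adjusted exposure effect
#'
#' Weighted logistic regression of the outcome on the exposure alone, the
#' weights building the pseudo-population in which covariates are balanced
#' between exposure groups. The exposure coefficient is the marginal
#' (population-average) adjusted log odds ratio. The default standard error
#' is the robust sandwich (HC0) estimate, which treats the weights as fixed;
#' bootstrap resampling (see [bootstrap_decomposition()]) is the alternative
#' that also propagates propensity-model uncertainty.
#'
#' @param cohort A [cohort()].
#' @param weights A `propensity_weights` object from [estimate_propensity()],
#'   or a positive numeric vector aligned with the cohort rows. Defaults to
#'   stabilized weights estimated from the cohort.
#' @param se `"robust"` (default) or `"none"`.
#' @return An `effect_fit` with `model_kind = "ipw"`.
#' @export
fit_ipw <- function(cohort, weights = NULL, se = c("robust", "none")) {
  stopifnot(inherits(cohort, "cohort"))
  se <- match.arg(se)
  .check_not_constant(cohort$exposure, "exposure")
  .check_not_constant(cohort$outcome, "outcome")
  if (is.null(weights)) weights <- estimate_propensity(cohort)
  w <- if (inherits(weights, "propensity_weights")) weights$weights else as.numeric(weights)
  if (length(w) != length(cohort$exposure)) {
    stop("weights (", length(w), ") are not aligned with cohort rows (",
         length(cohort$exposure), ")")
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be positive and finite")
  }
  d <- data.frame(y = cohort$outcome, x = cohort$exposure, .w = w)
  fam <- if (cohort$outcome_type == "binary") stats::quasibinomial() else stats::gaussian()
  fit <- stats::glm(y ~ x, family = fam, data = d, weights = .w)
  .fit_to_result(fit, "ipw", nrow(d),
                 se_from = if (se == "robust") "sandwich" else "none")
}

#' G-computation (standardization) marginal exposure effect
#'
#' Fits the multivariable outcome model, predicts every subject's outcome
#' probability with exposure forced to 1 and to 0, and contrasts the two
#' standardized risks on the log-odds scale:
#' `logit(mean(p1)) - logit(mean(p0))`. Like IPW this targets the marginal
#' (population-average) log odds ratio; with no covariates it equals the
#' unadjusted estimate exactly.
#'
#' @param cohort A [cohort()].
#' @return An `effect_fit` with `model_kind = "gcomputation"`; the standard
#'   error is absent (use the bootstrap for uncertainty).
#' @export
fit_gcomputation <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  mv <- fit_multivariable(cohort)
  fit <- mv$glm_fit
  d1 <- d0 <- fit$model
  d1$x <- 1; d0$x <- 0
  p1 <- mean(stats::predict(fit, newdata = d1, type = "response"))
  p0 <- mean(stats::predict(fit, newdata = d0, type = "response"))
  est <- if (cohort$outcome_type == "binary") {
    stats::qlogis(p1) - stats::qlogis(p0)
  } else {
    p1 - p0
  }
  new_effect_fit("gcomputation", est, intercept = mv$intercept,
                 covariate_coefficients = mv$covariate_coefficients,
                 standard_error = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, converged = mv$converged,
                 n_used = mv$n_used, glm_fit = fit, note = mv$note)
}

#' Estimate the full effect triplet
#'
#' Runs the three estimators on one cohort and collects the exposure
#' coefficients: `beta1` (univariable, unadjusted), `beta1_prime`
#' (multivariable, conditional adjusted) and `beta1_star` (IPW, marginal
#' adjusted). This triplet is the input to [decompose()].
#'
#' @param cohort A [cohort()].
#' @param stabilized Use stabilized IPW weights (default `TRUE`).
#' @return An object of class `effect_triplet` holding the three
#'   coefficients and the underlying fits.
#' @examples
#' ch <- generate_cohort(generation_params(1000, 0.92, 0.92, 0.92, seed = 3))
#' estimate_effects(ch)
#' @export
estimate_effects <- function(cohort, stabilized = TRUE) {
  uni <- fit_univariable(cohort)
  mv <- fit_multivariable(cohort)
  pw <- estimate_propensity(cohort, stabilized = stabilized)
  ipw <- fit_ipw(cohort, pw)
  structure(list(beta1 = uni$exposure_coefficient,
                 beta1_prime = mv$exposure_coefficient,
                 beta1_star = ipw$exposure_coefficient,
                 fits = list(univariable = uni, multivariable = mv, ipw = ipw),
                 converged = uni$converged && mv$converged && ipw$converged),
            class = "effect_triplet")
}

#' @export
print.effect_triplet <- function(x, ...) {
  cat("Exposure effect estimates (log odds ratios):\n")
  cat(sprintf("  beta1  (unadjusted, univariable)     %8.4f\n", x$beta1))
  cat(sprintf("  beta1' (conditional, multivariable)  %8.4f\n", x$beta1_prime))
  cat(sprintf("  beta1* (marginal, IPW)               %8.4f\n", x$beta1_star))
  if (!x$converged) cat("  WARNING: at least one fit did not converge\n")
  invisible(x)
}

# Fast IRLS path used by the bootstrap and the study runner: point estimates
# only, no formula/vcov overhead. Coefficients coincide with stats::glm
# because both run the same glm.fit IRLS.
.triplet_fast <- function(C, x, y) {
  n <- length(x)
  one <- rep(1, n)
  fam <- stats::binomial()
  f_uni <- stats::glm.fit(cbind(one, x), y, family = fam)
  Xmv <- cbind(one, x, C)
  f_mv <- stats::glm.fit(Xmv, y, family = fam)
  f_ps <- stats::glm.fit(cbind(one, C), x, family = fam)
  ps <- f_ps$fitted.values
  p <- mean(x)
  w <- ifelse(x == 1, p / ps, (1 - p) / (1 - ps))
  # quasibinomial: same IRLS solution, no non-integer-weight warning
  f_ipw <- stats::glm.fit(cbind(one, x), y, weights = w,
                          family = stats::quasibinomial())
  betas <- c(beta1 = unname(f_uni$coefficients[2]),
             beta1_prime = unname(f_mv$coefficients[2]),
             beta1_star = unname(f_ipw$coefficients[2]))
  ok <- f_uni$converged && f_mv$converged && f_ps$converged && f_ipw$converged &&
    all(is.finite(betas)) &&
    !any(f_mv$fitted.values < 1e-8 | f_mv$fitted.values > 1 - 1e-8) &&
    !any(f_uni$fitted.values < 1e-8 | f_uni$fitted.values > 1 - 1e-8)
  c(betas, converged = as.numeric(ok))
}
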