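# Large-sample limits of the three estimands by 1-D Gauss-Hermite
# quadrature. Because every covariate carries the same coefficient, the
# data-generating process depends on the covariates only through their sum
# s = C1 + ... + Ck ~ Normal(0, k), so every population expectation reduces
# to a one-dimensional integral over s.

# E over s ~ Normal(0, sigma2) of f(s), fixed-order Gauss-Hermite.
.gh_cache <- new.env(parent = emptyenv())

.expect_normal <- function(f, sigma2, nodes = 128) {
  key <- as.character(nodes)
  if (is.null(.gh_cache[[key]])) .gh_cache[[key]] <- pracma::gaussHermite(nodes)
  gh <- .gh_cache[[key]]
  s <- sqrt(2 * sigma2) * gh$x
  sum(gh$w * f(s)) / sqrt(pi)
}

#' Population marginal risk under a fixed exposure level
#'
#' The probability of the outcome if the whole population were set to
#' exposure level `x`, under the data-generating process of
#' [generation_params()]:
#' the expectation of `plogis(intercept_outcome + beta_xy * x + beta_cy * s)`
#' over `s ~ Normal(0, n_covariates)`, the distribution of the covariate
#' sum. Evaluated by fixed-order Gauss-Hermite quadrature. This is the
#' estimand that IPW and G-computation standardize to.
#'
#' @param exposure_value 0 or 1.
#' @param params A [generation_params()].
#' @param nodes Number of quadrature nodes (default 128).
#' @return A probability.
#' @examples
#' p <- generation_params(100, beta_xy = 0.92)
#' marginal_risk(1, p)  # plogis(0.92), no covariate effect on outcome
#' @export
marginal_risk <- function(exposure_value, params, nodes = 128) {
  stopifnot(inherits(params, "generation_params"),
            exposure_value %in% c(0, 1))
  .expect_normal(function(s) {
    stats::plogis(params$intercept_outcome + params$beta_xy * exposure_value +
                    params$beta_cy * s)
  }, sigma2 = params$n_covariates, nodes = nodes)
}

#' Large-sample limits of the three exposure-effect estimands
#'
#' Computes, for one data-generating condition, the limits to which the
#' three estimators converge:
#' \describe{
#'   \item{conditional_logor}{the multivariable estimand; equals `beta_xy`
#'     under correct specification,}
#'   \item{marginal_logor}{the IPW / G-computation estimand,
#'     `logit(marginal_risk(1)) - logit(marginal_risk(0))`,}
#'   \item{unadjusted_logor}{the univariable estimand,
#'     `logit(E[Y|X=1]) - logit(E[Y|X=0])`, with the conditional exposure
#'     distribution induced by the propensity model.}
#' }
#' together with the limiting confounding bias (unadjusted minus marginal),
#' the limiting noncollapsibility effect (marginal minus conditional), and
#' the fixed latent residual variance of the logistic model, pi^2/3. All
#' integrals are one-dimensional Gauss-Hermite quadratures over the
#' covariate sum. These limits serve as an independent oracle for simulation
#' results: the odds ratio is noncollapsible, so `|marginal_logor| <
#' |conditional_logor|` whenever both `beta_xy` and `beta_cy` are nonzero.
#'
#' @param params A [generation_params()].
#' @param nodes Number of quadrature nodes (default 128).
#' @return An object of class `theoretical_effects`.
#' @examples
#' theoretical_effects(generation_params(100, 0.92, 0.92, 0.92))
#' @export
theoretical_effects <- function(params, nodes = 128) {
  stopifnot(inherits(params, "generation_params"))
  k <- params$n_covariates
  m1 <- marginal_risk(1, params, nodes)
  m0 <- marginal_risk(0, params, nodes)
  marginal <- stats::qlogis(m1) - stats::qlogis(m0)

  pr_x <- function(s, x) {
    p <- stats::plogis(params$intercept_exposure + params$lambda_cx * s)
    if (x == 1) p else 1 - p
  }
  ey_given_x <- function(x) {
    num <- .expect_normal(function(s) {
      stats::plogis(params$intercept_outcome + params$beta_xy * x +
                      params$beta_cy * s) * pr_x(s, x)
    }, k, nodes)
    den <- .expect_normal(function(s) pr_x(s, x), k, nodes)
    num / den
  }
  unadjusted <- stats::qlogis(ey_given_x(1)) - stats::qlogis(ey_given_x(0))
  conditional <- params$beta_xy
  structure(list(conditional_logor = conditional,
                 marginal_logor = marginal,
                 unadjusted_logor = unadjusted,
                 confounding_bias_limit = unadjusted - marginal,
                 noncollapsibility_limit = marginal - conditional,
                 latent_residual_variance = pi^2 / 3),
            class = "theoretical_effects")
}

#' @export
print.theoretical_effects <- function(x, ...) {
  cat("Large-sample limits (log odds ratios):\n")
  cat(sprintf("  unadjusted  (beta1 limit)   %8.4f\n", x$unadjusted_logor))
  cat(sprintf("  conditional (beta1' limit)  %8.4f\n", x$conditional_logor))
  cat(sprintf("  marginal    (beta1* limit)  %8.4f\n", x$marginal_logor))
  cat(sprintf("  confounding bias limit      %8.4f\n", x$confounding_bias_limit))
  cat(sprintf("  noncollapsibility limit     %8.4f\n", x$noncollapsibility_limit))
  cat(sprintf("  latent residual variance    %8.4f (pi^2/3, displayed as %.2f)\n",
              x$latent_residual_variance, round(x$latent_residual_variance, 2)))
  invisible(x)
}

#' Latent-variance diagnostic for a logistic fit
#'
#' In the latent-variable view of logistic regression the residual variance
#' is fixed at pi^2/3 (about 3.29). Adding outcome-associated covariates
#' therefore cannot shrink the residual variance; it inflates the explained
#' variance (the variance of the linear predictor) and with it the total
#' latent variance, rescaling every coefficient. This diagnostic exposes
#' that mechanism: it reports the explained variance of the fitted linear
#' predictor, the fixed residual pi^2/3, and their sum.
#'
#' @param fit An `effect_fit` from a logistic model, or a fitted `glm` with
#'   binomial/quasibinomial family and logit link.
#' @return A list with `explained_variance`, `residual_variance`,
#'   `total_latent_variance`, of class `latent_variance_report`.
#' @examples
#' ch <- generate_cohort(generation_params(500, 0.92, 0.92, 0.92, seed = 2))
#' latent_variance_report(fit_multivariable(ch))
#' @export
latent_variance_report <- function(fit) {
  g <- if (inherits(fit, "effect_fit")) fit$glm_fit else fit
  if (!inherits(g, "glm")) stop("'fit' must be an effect_fit or glm object")
  fam <- stats::family(g)
  if (!fam$family %in% c("binomial", "quasibinomial") ||
      fam$link != "logit") {
    stop("latent variance diagnostic applies only to logistic (logit-link) fits")
  }
  if (inherits(fit, "effect_fit") && !fit$converged) {
    stop("fit did not converge; diagnostic not meaningful")
  }
  eta <- stats::predict(g, type = "link")
  n <- length(eta)
  explained <- stats::var(eta) * (n - 1) / n  # population variance of eta
  resid_var <- pi^2 / 3
  structure(list(explained_variance = explained,
                 residual_variance = resid_var,
                 total_latent_variance = explained + resid_var),
            class = "latent_variance_report")
}

#' @export
print.latent_variance_report <- function(x, ...) {
  cat("Latent-scale variance decomposition:\n")
  cat(sprintf("  explained (var of linear predictor) %8.4f\n", x$explained_variance))
  cat(sprintf("  residual  (fixed, pi^2/3)           %8.4f (%.2f)\n",
              x$residual_variance, round(x$residual_variance, 2)))
  cat(sprintf("  total latent variance               %8.4f\n", x$total_latent_variance))
  invisible(x)
}
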