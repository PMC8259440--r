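#' Decompose the change in estimate into confounding bias and
#' noncollapsibility
#'
#' Given the three exposure coefficients from one cohort — the unadjusted
#' `beta1`, the conditional multivariable-adjusted `beta1_prime` and the
#' marginal IPW-adjusted `beta1_star` — computes
#' \describe{
#'   \item{change in estimate}{`beta1_prime - beta1`, the quantity the
#'     10\%-rule inspects,}
#'   \item{confounding bias}{`beta1 - beta1_star`, the component caused by
#'     covariates associated with both exposure and outcome,}
#'   \item{noncollapsibility effect}{`beta1_star - beta1_prime`, the scale
#'     change from adding outcome-associated covariates to a logistic model
#'     (not a bias).}
#' }
#' The identity `confounding_bias + noncollapsibility_effect =
#' -change_in_estimate` holds exactly. Percent changes are relative to
#' `|beta1|` and reported as `NA` when `beta1 = 0`. The 10\% flag mirrors
#' the conventional change-in-estimate criterion; that criterion is known to
#' conflate the two components and its use is not recommended.
#'
#' @param triplet An `effect_triplet` from [estimate_effects()], or the
#'   unadjusted coefficient `beta1` if the three coefficients are supplied
#'   as numbers.
#' @param beta1_prime,beta1_star Multivariable and IPW coefficients, used
#'   only when `triplet` is numeric.
#' @return An object of class `effect_decomposition`.
#' @examples
#' decompose(0.90, 0.93, 0.99)  # -0.09 confounding bias, 0.06 noncollapsibility
#' @export
decompose <- function(triplet, beta1_prime = NULL, beta1_star = NULL) {
  if (inherits(triplet, "effect_triplet")) {
    b1 <- triplet$beta1; b1p <- triplet$beta1_prime; b1s <- triplet$beta1_star
  } else {
    b1 <- triplet; b1p <- beta1_prime; b1s <- beta1_star
  }
  vals <- c(beta1 = b1, beta1_prime = b1p, beta1_star = b1s)
  if (length(vals) != 3 || !all(is.finite(vals))) {
    stop("decompose() needs three finite coefficients (beta1, beta1_prime, beta1_star)")
  }
  pc <- if (b1 == 0) NA_real_ else 100 * abs(b1p - b1) / abs(b1)
  pcf <- if (b1 == 0) NA_real_ else 100 * abs(b1 - b1s) / abs(b1)
  structure(list(beta1 = b1, beta1_prime = b1p, beta1_star = b1s,
                 change_in_estimate = b1p - b1,
                 confounding_bias = b1 - b1s,
                 noncollapsibility_effect = b1s - b1p,
                 percent_change = pc,
                 percent_confounding = pcf,
                 flagged_by_10pct_rule = isTRUE(pc >= 10)),
            class = "effect_decomposition")
}

#' @export
print.effect_decomposition <- function(x, ...) {
  cat("Decomposition of the change in estimate (log-odds scale):\n")
  cat(sprintf("  change in estimate    (beta1' - beta1)  %8.4f\n", x$change_in_estimate))
  cat(sprintf("  confounding bias      (beta1 - beta1*)  %8.4f\n", x$confounding_bias))
  cat(sprintf("  noncollapsibility     (beta1* - beta1') %8.4f\n", x$noncollapsibility_effect))
  if (!is.na(x$percent_change)) {
    cat(sprintf("  percent change %.1f%%; percent confounding %.1f%%\n",
                x$percent_change, x$percent_confounding))
    cat(sprintf("  10%%-rule flag: %s (note: the change-in-estimate criterion is not\n",
                if (x$flagged_by_10pct_rule) "TRIGGERED" else "not triggered"))
    cat("  recommended in logistic regression; it conflates confounding with\n")
    cat("  the noncollapsibility effect)\n")
  } else {
    cat("  percent changes undefined (beta1 = 0)\n")
  }
  invisible(x)
}

#' @export
as.data.frame.effect_decomposition <- function(x, ...) {
  data.frame(statistic = c("change_in_estimate", "confounding_bias",
                           "noncollapsibility_effect"),
             estimate = c(x$change_in_estimate, x$confounding_bias,
                          x$noncollapsibility_effect))
}

#' Percentile bootstrap for the decomposition statistics
#'
#' Resamples subjects with replacement, refits the three estimators on each
#' resample, and returns percentile 95\% confidence intervals for the change
#' in estimate, the confounding bias and the noncollapsibility effect. The
#' point estimates come from the original cohort. Resamples whose fits do
#' not converge (e.g. separation) are discarded and counted; if more than
#' 10\% fail the result is flagged unreliable.
#'
#' @param cohort A [cohort()] with a binary outcome.
#' @param n_resamples Number of bootstrap resamples (default 1000).
#' @param seed Integer seed; fixed seed gives identical intervals.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `bootstrap_decomposition`: a data frame with
#'   one row per statistic (`point`, `ci_low`, `ci_high`), plus attributes
#'   `n_resamples`, `n_failed`, `seed` and `unreliable`.
#' @examples
#' ch <- generate_cohort(generation_params(300, 0.92, 0.92, 0.92, seed = 5))
#' bootstrap_decomposition(ch, n_resamples = 50, seed = 1)
#' @export
bootstrap_decomposition <- function(cohort, n_resamples = 1000, seed = 1L,
                                    conf_level = 0.95) {
  stopifnot(inherits(cohort, "cohort"), cohort$outcome_type == "binary")
  if (!is.numeric(n_resamples) || n_resamples < 1) {
    stop("'n_resamples' must be at least 1")
  }
  n <- length(cohort$exposure)
  point <- decompose(estimate_effects(cohort))
  set.seed(seed)
  stats_mat <- matrix(NA_real_, nrow = n_resamples, ncol = 3,
                      dimnames = list(NULL, c("change_in_estimate",
                                              "confounding_bias",
                                              "noncollapsibility_effect")))
  n_failed <- 0L
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(n, n, replace = TRUE)
    tri <- tryCatch(
      .triplet_fast(cohort$covariates[idx, , drop = FALSE],
                    cohort$exposure[idx], cohort$outcome[idx]),
      error = function(e) NULL)
    if (is.null(tri) || tri[["converged"]] != 1) {
      n_failed <- n_failed + 1L
      next
    }
    stats_mat[b, ] <- c(tri[["beta1_prime"]] - tri[["beta1"]],
                        tri[["beta1"]] - tri[["beta1_star"]],
                        tri[["beta1_star"]] - tri[["beta1_prime"]])
  }
  alpha <- (1 - conf_level) / 2
  ok <- stats_mat[stats::complete.cases(stats_mat), , drop = FALSE]
  ci <- if (nrow(ok) == 0) {
    matrix(NA_real_, 2, 3)
  } else {
    apply(ok, 2, stats::quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  }
  out <- data.frame(
    statistic = colnames(stats_mat),
    point = c(point$change_in_estimate, point$confounding_bias,
              point$noncollapsibility_effect),
    ci_low = ci[1, ], ci_high = ci[2, ], row.names = NULL)
  structure(out, class = c("bootstrap_decomposition", "data.frame"),
            n_resamples = as.integer(n_resamples), n_failed = n_failed,
            seed = as.integer(seed),
            unreliable = n_failed > 0.1 * n_resamples,
            resamples = stats_mat)
}

#' @export
print.bootstrap_decomposition <- function(x, ...) {
  cat(sprintf("Percentile bootstrap (%d resamples, %d failed):\n",
              attr(x, "n_resamples"), attr(x, "n_failed")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  if (isTRUE(attr(x, "unreliable"))) {
    cat("WARNING: more than 10% of resamples failed to converge; intervals unreliable\n")
  }
  invisible(x)
}
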