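#' Define a factorial Monte Carlo study grid
#'
#' The full factorial design crosses one set of effect values — applied to
#' each of the exposure-outcome, covariate-exposure and covariate-outcome
#' effects — with a set of sample sizes. The defaults are the seven effect
#' values (zero, and positive/negative small 0.38, medium 0.92, large 1.42)
#' and the four sample sizes 250, 500, 750 and 1000, giving
#' 7 x 7 x 7 x 4 = 1372 conditions. The default desk-scale repetition count
#' is 100; the full-scale study uses 1000.
#'
#' @param effect_values Numeric vector of effect sizes (log-odds).
#' @param sample_sizes Integer vector of cohort sizes.
#' @param repetitions Replications per condition.
#' @param master_seed Integer master seed; per-replication seeds are derived
#'   deterministically from it and the condition index, so any single
#'   replication can be re-run in isolation.
#' @return An object of class `study_grid`.
#' @examples
#' g <- study_grid()
#' nrow(enumerate_conditions(g))  # 1372
#' @export
study_grid <- function(effect_values = c(-1.42, -0.92, -0.38, 0, 0.38, 0.92, 1.42),
                       sample_sizes = c(250L, 500L, 750L, 1000L),
                       repetitions = 100L, master_seed = 20210705L) {
  if (length(effect_values) == 0 || length(sample_sizes) == 0) {
    stop("effect_values and sample_sizes must be non-empty")
  }
  if (any(sample_sizes < 1)) stop("sample_sizes must be positive")
  if (repetitions < 1) stop("repetitions must be at least 1")
  structure(list(effect_values = sort(unique(effect_values)),
                 sample_sizes = sort(unique(as.integer(sample_sizes))),
                 repetitions = as.integer(repetitions),
                 master_seed = as.integer(master_seed)),
            class = "study_grid")
}

#' Enumerate all conditions of a study grid
#'
#' Produces the full factorial product in a deterministic order (exposure-
#' outcome effect varying fastest, then covariate-exposure, covariate-
#' outcome, then sample size), with a stable 1-based condition index.
#'
#' @param grid A [study_grid()].
#' @return A data frame with columns `condition`, `beta_xy`, `lambda_cx`,
#'   `beta_cy`, `n`, `scenario`.
#' @export
enumerate_conditions <- function(grid) {
  stopifnot(inherits(grid, "study_grid"))
  d <- expand.grid(beta_xy = grid$effect_values,
                   lambda_cx = grid$effect_values,
                   beta_cy = grid$effect_values,
                   n = grid$sample_sizes,
                   KEEP.OUT.ATTRS = FALSE)
  d <- cbind(condition = seq_len(nrow(d)), d)
  d$scenario <- mapply(classify_scenario, d$beta_xy, d$lambda_cx, d$beta_cy)
  d
}

#' Classify a condition into its causal-diagram scenario
#'
#' Four scenarios describe which of the two phenomena a condition exhibits:
#' \describe{
#'   \item{A}{covariates affect exposure and outcome, exposure affects
#'     outcome: both confounding bias and a noncollapsibility effect;}
#'   \item{B}{covariates affect exposure and outcome but exposure does not
#'     affect outcome: confounding without noncollapsibility;}
#'   \item{C}{covariates affect only the outcome: noncollapsibility without
#'     confounding;}
#'   \item{D}{covariates do not affect the outcome: neither (strict
#'     collapsibility — all three estimates coincide).}
#' }
#' The combination `lambda_cx = 0, beta_cy != 0, beta_xy = 0` falls outside
#' this taxonomy (neither phenomenon manifests, yet the covariates are
#' outcome-associated) and is labelled `"C-degenerate"`.
#'
#' @param beta_xy,lambda_cx,beta_cy Effect values, or a single
#'   [generation_params()] object as the first argument.
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`, `"C-degenerate"`.
#' @examples
#' classify_scenario(0.92, 0.92, 0.92)  # "A"
#' classify_scenario(0.92, 0.38, 0)     # "D"
#' @export
classify_scenario <- function(beta_xy, lambda_cx = NULL, beta_cy = NULL) {
  if (inherits(beta_xy, "generation_params")) {
    p <- beta_xy
    beta_xy <- p$beta_xy; lambda_cx <- p$lambda_cx; beta_cy <- p$beta_cy
  }
  if (beta_cy == 0) return("D")
  if (lambda_cx != 0 && beta_xy != 0) return("A")
  if (lambda_cx != 0 && beta_xy == 0) return("B")
  if (lambda_cx == 0 && beta_xy != 0) return("C")
  "C-degenerate"
}

# Deterministic per-replication seed: unique per (condition, rep) for any
# master seed, computed exactly in doubles (< 2^53) and kept below 2^31.
.derive_seed <- function(master_seed, condition, rep) {
  as.integer((abs(master_seed) + condition * 2654435761 + rep * 97) %% 2147483647)
}

#' Run the Monte Carlo study
#'
#' For every condition (optionally a subset, keyed by the stable condition
#' index, which makes interrupted runs resumable), generates `repetitions`
#' cohorts with deterministically derived seeds, fits the univariable,
#' multivariable and IPW estimators, decomposes the effects, and averages
#' over the converged replications. Replications with non-converged fits
#' (e.g. separation) are excluded from the means and counted.
#'
#' @param grid A [study_grid()].
#' @param conditions Optional integer vector of condition indices to run
#'   (default: all).
#' @param n_covariates Number of covariates per cohort (default 3).
#' @param verbose Print progress every 50 conditions.
#' @return A data frame of class `study_summary`, one row per condition,
#'   with replication means of the three coefficients and the three
#'   decomposition statistics, Monte Carlo standard errors of the
#'   decomposition statistics (`se_*`), the scenario label and convergence
#'   counts.
#' @examples
#' g <- study_grid(effect_values = c(0, 0.92), sample_sizes = 250,
#'                 repetitions = 20, master_seed = 1)
#' run_study(g)
#' @export
run_study <- function(grid, conditions = NULL, n_covariates = 3,
                      verbose = FALSE) {
  stopifnot(inherits(grid, "study_grid"))
  cond <- enumerate_conditions(grid)
  if (!is.null(conditions)) {
    bad <- setdiff(conditions, cond$condition)
    if (length(bad)) stop("unknown condition indices: ", paste(bad, collapse = ", "))
    cond <- cond[cond$condition %in% conditions, , drop = FALSE]
  }
  reps <- grid$repetitions
  out <- vector("list", nrow(cond))
  for (i in seq_len(nrow(cond))) {
    ci <- cond[i, ]
    res <- matrix(NA_real_, nrow = reps, ncol = 3,
                  dimnames = list(NULL, c("beta1", "beta1_prime", "beta1_star")))
    n_failed <- 0L
    for (r in seq_len(reps)) {
      p <- generation_params(ci$n, beta_xy = ci$beta_xy,
                             lambda_cx = ci$lambda_cx, beta_cy = ci$beta_cy,
                             n_covariates = n_covariates,
                             seed = .derive_seed(grid$master_seed, ci$condition, r))
      ch <- generate_cohort(p)
      tri <- tryCatch(.triplet_fast(ch$covariates, ch$exposure, ch$outcome),
                      error = function(e) NULL)
      if (is.null(tri) || tri[["converged"]] != 1) {
        n_failed <- n_failed + 1L
        next
      }
      res[r, ] <- tri[1:3]
    }
    okr <- res[stats::complete.cases(res), , drop = FALSE]
    if (nrow(okr) == 0) {
      warning("condition ", ci$condition, " had zero converged replications")
      m <- c(beta1 = NA_real_, beta1_prime = NA_real_, beta1_star = NA_real_)
      dstats <- matrix(NA_real_, 0, 3)
    } else {
      m <- colMeans(okr)
      dstats <- cbind(change = okr[, "beta1_prime"] - okr[, "beta1"],
                      bias = okr[, "beta1"] - okr[, "beta1_star"],
                      noncollapse = okr[, "beta1_star"] - okr[, "beta1_prime"])
    }
    mc_se <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
    out[[i]] <- data.frame(
      condition = ci$condition, beta_xy = ci$beta_xy,
      lambda_cx = ci$lambda_cx, beta_cy = ci$beta_cy, n = ci$n,
      scenario = ci$scenario,
      mean_beta1 = m[["beta1"]], mean_beta1_prime = m[["beta1_prime"]],
      mean_beta1_star = m[["beta1_star"]],
      mean_change = if (nrow(dstats)) mean(dstats[, "change"]) else NA_real_,
      mean_confounding_bias = if (nrow(dstats)) mean(dstats[, "bias"]) else NA_real_,
      mean_noncollapsibility = if (nrow(dstats)) mean(dstats[, "noncollapse"]) else NA_real_,
      se_change = if (nrow(dstats)) mc_se(dstats[, "change"]) else NA_real_,
      se_confounding_bias = if (nrow(dstats)) mc_se(dstats[, "bias"]) else NA_real_,
      se_noncollapsibility = if (nrow(dstats)) mc_se(dstats[, "noncollapse"]) else NA_real_,
      se_beta1 = mc_se(okr[, "beta1"]),
      se_beta1_prime = mc_se(okr[, "beta1_prime"]),
      se_beta1_star = mc_se(okr[, "beta1_star"]),
      n_converged = nrow(okr), n_failed = n_failed)
    if (verbose && i %% 50 == 0) {
      message("completed ", i, " / ", nrow(cond), " conditions")
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("study_summary", "data.frame")
  res
}

#' Summarize sign and monotonicity patterns of a study
#'
#' Aggregates condition summaries into three plotting-ready tables:
#' \describe{
#'   \item{confounding_by_effects}{mean confounding bias as a function of
#'     the covariate-outcome effect, one series per covariate-exposure
#'     effect (averaged over the other factors);}
#'   \item{noncollapsibility_by_effects}{mean noncollapsibility effect as a
#'     function of the covariate-outcome effect, one series per
#'     exposure-outcome effect;}
#'   \item{sign_table}{cross-tabulation of the signs of the change in
#'     estimate, the confounding bias and the noncollapsibility effect.}
#' }
#' Signs are taken as zero when the mean is within `zero_tol` of zero, so
#' Monte Carlo noise around a true zero does not masquerade as a sign.
#'
#' @param summaries A `study_summary` from [run_study()].
#' @param zero_tol Absolute tolerance below which a mean counts as zero
#'   (default 0.02 on the log-odds scale).
#' @return A list with the three tables.
#' @export
summarize_patterns <- function(summaries, zero_tol = 0.02) {
  stopifnot(inherits(summaries, "data.frame"), nrow(summaries) > 0)
  s <- summaries[!is.na(summaries$mean_beta1), , drop = FALSE]

  fig2 <- stats::aggregate(mean_confounding_bias ~ beta_cy + lambda_cx,
                           data = s, FUN = mean)
  names(fig2)[3] <- "confounding_bias"
  fig3 <- stats::aggregate(mean_noncollapsibility ~ beta_cy + beta_xy,
                           data = s, FUN = mean)
  names(fig3)[3] <- "noncollapsibility_effect"

  sgn <- function(v) ifelse(abs(v) <= zero_tol, "zero",
                            ifelse(v > 0, "positive", "negative"))
  sign_table <- as.data.frame(table(
    change = sgn(s$mean_change),
    confounding_bias = sgn(s$mean_confounding_bias),
    noncollapsibility = sgn(s$mean_noncollapsibility)))
  sign_table <- sign_table[sign_table$Freq > 0, , drop = FALSE]
  row.names(sign_table) <- NULL
  list(confounding_by_effects = fig2,
       noncollapsibility_by_effects = fig3,
       sign_table = sign_table)
}
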