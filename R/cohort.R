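#' Data-generating parameters for one simulation condition
#'
#' Bundles the true coefficients of the data-generating process: covariates
#' are i.i.d. standard normal, exposure is Bernoulli with a logistic link on
#' the covariate sum, and the outcome is Bernoulli with a logistic link on
#' exposure and the covariate sum. One shared coefficient per effect type is
#' used across covariates.
#'
#' @param n_subjects Positive integer, number of subjects.
#' @param beta_xy True exposure-to-outcome effect (log-odds).
#' @param lambda_cx True covariate-to-exposure effect, shared by all
#'   covariates (log-odds per covariate unit).
#' @param beta_cy True covariate-to-outcome effect, shared by all covariates
#'   (log-odds per covariate unit).
#' @param n_covariates Positive integer, number of covariates (default 3).
#' @param intercept_exposure Intercept of the exposure model (log-odds).
#' @param intercept_outcome Intercept of the outcome model (log-odds).
#' @param seed Integer random seed.
#' @return An object of class `generation_params`.
#' @examples
#' generation_params(250, beta_xy = 0.92, lambda_cx = 0.92, beta_cy = 0.92, seed = 1)
#' @export
generation_params <- function(n_subjects, beta_xy = 0, lambda_cx = 0,
                              beta_cy = 0, n_covariates = 3,
                              intercept_exposure = 0, intercept_outcome = 0,
                              seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1 ||
      is.na(n_subjects) || n_subjects < 1 || n_subjects != floor(n_subjects)) {
    stop("'n_subjects' must be a positive integer (got ",
         deparse(substitute(n_subjects)), " = ", format(n_subjects), ")")
  }
  if (!is.numeric(n_covariates) || length(n_covariates) != 1 ||
      n_covariates < 1 || n_covariates != floor(n_covariates)) {
    stop("'n_covariates' must be a positive integer")
  }
  coefs <- c(beta_xy = beta_xy, lambda_cx = lambda_cx, beta_cy = beta_cy,
             intercept_exposure = intercept_exposure,
             intercept_outcome = intercept_outcome)
  if (!all(is.finite(coefs))) {
    stop("all coefficients must be finite; offending: ",
         paste(names(coefs)[!is.finite(coefs)], collapse = ", "))
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_covariates = as.integer(n_covariates),
                 beta_xy = beta_xy, lambda_cx = lambda_cx, beta_cy = beta_cy,
                 intercept_exposure = intercept_exposure,
                 intercept_outcome = intercept_outcome,
                 seed = as.integer(seed)),
            class = "generation_params")
}

#' @export
print.generation_params <- function(x, ...) {
  cat("Data-generating parameters:\n")
  cat(sprintf("  n = %d subjects, %d standard-normal covariates\n",
              x$n_subjects, x$n_covariates))
  cat(sprintf("  exposure ~ logit^-1(%g + %g * sum(C))\n",
              x$intercept_exposure, x$lambda_cx))
  cat(sprintf("  outcome  ~ logit^-1(%g + %g * X + %g * sum(C))\n",
              x$intercept_outcome, x$beta_xy, x$beta_cy))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}

#' Construct a cohort
#'
#' A cohort holds a numeric covariate matrix, a binary exposure vector and
#' an outcome vector of equal length. Outcomes are binary for the logistic
#' workflow; `outcome_type = "continuous"` is accepted so the identity-link
#' (linear regression) collapsibility check can be run on the same machinery.
#'
#' @param covariates Numeric matrix, one row per subject (zero columns
#'   allowed, meaning no measured covariates).
#' @param exposure Vector of 0/1 exposure indicators.
#' @param outcome Vector of outcomes; 0/1 unless `outcome_type = "continuous"`.
#' @param outcome_type `"binary"` (default) or `"continuous"`.
#' @return An object of class `cohort`.
#' @export
cohort <- function(covariates, exposure, outcome,
                   outcome_type = c("binary", "continuous")) {
  outcome_type <- match.arg(outcome_type)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) == 0 && length(exposure) > 0) {
    covariates <- matrix(numeric(0), nrow = length(exposure), ncol = 0)
  }
  storage.mode(covariates) <- "double"
  n <- length(exposure)
  if (length(outcome) != n || nrow(covariates) != n) {
    stop("row counts disagree: ", nrow(covariates), " covariate rows, ",
         n, " exposure values, ", length(outcome), " outcome values")
  }
  if (!all(exposure %in% c(0, 1))) {
    stop("column 'x': exposure must contain only 0/1 values")
  }
  if (outcome_type == "binary" && !all(outcome %in% c(0, 1))) {
    stop("column 'y': outcome must contain only 0/1 values")
  }
  if (anyNA(covariates) || !is.numeric(covariates)) {
    stop("covariates must be numeric and complete")
  }
  if (ncol(covariates) > 0 && is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("c", seq_len(ncol(covariates)))
  }
  structure(list(covariates = covariates,
                 exposure = as.integer(exposure),
                 outcome = if (outcome_type == "binary") as.integer(outcome) else as.double(outcome),
                 outcome_type = outcome_type),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d subjects, %d covariate(s); exposure prevalence %.3f",
              length(x$exposure), ncol(x$covariates), mean(x$exposure)))
  if (x$outcome_type == "binary") {
    cat(sprintf(", outcome prevalence %.3f\n", mean(x$outcome)))
  } else {
    cat(sprintf(", continuous outcome (mean %.3f)\n", mean(x$outcome)))
  }
  invisible(x)
}

#' @export
as.data.frame.cohort <- function(x, ...) {
  d <- data.frame(y = x$outcome, x = x$exposure)
  if (ncol(x$covariates) > 0) d <- cbind(d, as.data.frame(x$covariates))
  d
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` i.i.d. standard-normal covariates per subject, then a
#' Bernoulli exposure with success probability
#' `plogis(intercept_exposure + lambda_cx * sum(C))` and a Bernoulli outcome
#' with success probability
#' `plogis(intercept_outcome + beta_xy * X + beta_cy * sum(C))`.
#' The result is a pure function of `params` (including its seed).
#'
#' @param params A [generation_params()] object.
#' @return A [cohort()].
#' @examples
#' ch <- generate_cohort(generation_params(500, 0.92, 0.92, 0.92, seed = 7))
#' ch
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "generation_params"))
  set.seed(params$seed)
  n <- params$n_subjects
  k <- params$n_covariates
  C <- matrix(stats::rnorm(n * k), nrow = n, ncol = k,
              dimnames = list(NULL, paste0("c", seq_len(k))))
  s <- rowSums(C)
  x <- stats::rbinom(n, 1L, stats::plogis(params$intercept_exposure +
                                            params$lambda_cx * s))
  y <- stats::rbinom(n, 1L, stats::plogis(params$intercept_outcome +
                                            params$beta_xy * x +
                                            params$beta_cy * s))
  cohort(C, x, y)
}

#' Write a cohort to delimited text
#'
#' Layout: header `y,x,c1,...,ck`, one row per subject, comma-separated,
#' UTF-8, no index column. Covariates are serialized with 17 significant
#' digits so that [read_cohort()] reproduces the cohort bit-exactly.
#'
#' @param cohort A [cohort()].
#' @param destination File path to write.
#' @param sep Field separator (default `","`).
#' @export
write_cohort <- function(cohort, destination, sep = ",") {
  stopifnot(inherits(cohort, "cohort"))
  d <- data.frame(y = cohort$outcome, x = cohort$exposure,
                  check.names = FALSE)
  if (ncol(cohort$covariates) > 0) {
    Cchr <- apply(cohort$covariates, 2, formatC, digits = 17, format = "g")
    if (is.null(dim(Cchr))) Cchr <- matrix(Cchr, nrow = 1,
                                           dimnames = list(NULL, colnames(cohort$covariates)))
    d <- cbind(d, as.data.frame(Cchr, stringsAsFactors = FALSE))
  }
  utils::write.table(d, destination, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}

#' Read a cohort from delimited text
#'
#' Expects the layout written by [write_cohort()]: columns `y`, `x`, and
#' zero or more numeric covariate columns. Malformed columns are rejected
#' with a message naming the offender.
#'
#' @param source File path to read.
#' @param sep Field separator (default `","`).
#' @return A [cohort()].
#' @export
read_cohort <- function(source, sep = ",") {
  if (!file.exists(source)) stop("cohort file not found: ", source)
  d <- utils::read.table(source, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  for (col in c("y", "x")) {
    if (!col %in% names(d)) stop("missing required column '", col, "'")
    if (!all(d[[col]] %in% c(0, 1))) {
      stop("column '", col, "' contains non-binary values")
    }
  }
  covnames <- setdiff(names(d), c("y", "x"))
  for (col in covnames) {
    if (!is.numeric(d[[col]])) {
      stop("covariate column '", col, "' is not numeric")
    }
  }
  C <- as.matrix(d[, covnames, drop = FALSE])
  cohort(C, d$x, d$y)
}
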