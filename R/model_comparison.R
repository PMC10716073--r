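#' Compare the four information-value models by BIC
#'
#' For each candidate model, attaches its Information Value to every trial
#' (a continuous regressor determined by the trial's number of informative
#' windows), fits the logistic mixed model
#' `accept ~ info_value + (1 | subject_id)` — the baseline model reduces to
#' the subject-specific intercept alone, since its Information Value is
#' identically zero — and ranks the fits by the Bayesian information
#' criterion \eqn{-2\ell + k\log n}, with \eqn{n} the number of trial-level
#' observations. The winning model has the lowest BIC; `delta_bic` is its
#' margin over the runner-up.
#'
#' @param data Trial records with `choice`, `n_informative` and
#'   `subject_id` columns.
#' @param models Candidate model ids; default all four ([info_models()]).
#' @param nAGQ Quadrature nodes for [fit_choice_glmm()].
#' @return An object of class `info_model_comparison`: list with `fits`
#'   (named list of `choice_glmm` objects), `table` (data.frame: model_id,
#'   n_params, loglik, bic, delta_bic relative to the winner, converged),
#'   `winner` and `delta_bic` (winner's margin over the runner-up).
#'   Non-convergence of one model is flagged in the table, not fatal.
#' @examples
#' \donttest{
#' trials <- simulate_cohort(8, experiment = 1, seed = 3)
#' compare_info_models(trials)
#' }
#' @export
compare_info_models <- function(data, models = info_models(), nAGQ = 1) {
  models <- match.arg(models, info_models(), several.ok = TRUE)
  data <- prepare_choice_data(data)
  fits <- lapply(models, function(m) {
    data$info_value <- info_value(m, data$n_informative)
    fm <- if (m == "baseline") {
      accept ~ 1 + (1 | subject_id)
    } else {
      accept ~ info_value + (1 | subject_id)
    }
    tryCatch(fit_choice_glmm(fm, data, nAGQ = nAGQ),
             error = function(e) structure(list(error = conditionMessage(e)),
                                           class = "choice_glmm_failure"))
  })
  names(fits) <- models
  ok <- !vapply(fits, inherits, logical(1), "choice_glmm_failure")
  bic <- ifelse(ok, vapply(fits, function(f) {
    if (inherits(f, "choice_glmm")) f$bic else NA_real_
  }, numeric(1)), NA_real_)
  tab <- data.frame(
    model_id = models,
    n_params = vapply(fits, function(f) {
      if (inherits(f, "choice_glmm")) f$n_params else NA_integer_
    }, integer(1)),
    loglik = vapply(fits, function(f) {
      if (inherits(f, "choice_glmm")) f$loglik else NA_real_
    }, numeric(1)),
    bic = bic,
    converged = vapply(fits, function(f) {
      if (inherits(f, "choice_glmm")) f$converged else FALSE
    }, logical(1)),
    stringsAsFactors = FALSE
  )
  tab$delta_bic <- tab$bic - min(tab$bic, na.rm = TRUE)
  winner <- tab$model_id[which.min(tab$bic)]
  sorted <- sort(tab$bic[!is.na(tab$bic)])
  margin <- if (length(sorted) > 1L) sorted[2] - sorted[1] else NA_real_
  rownames(tab) <- NULL
  structure(list(fits = fits, table = tab, winner = winner,
                 delta_bic = margin),
            class = "info_model_comparison")
}

#' @export
print.info_model_comparison <- function(x, digits = 2, ...) {
  cat("Information-value model comparison (", nrow(x$table), " models, n = ",
      x$fits[[x$winner]]$n_obs, " trials)\n", sep = "")
  tab <- x$table
  tab$loglik <- round(tab$loglik, digits)
  tab$bic <- round(tab$bic, digits)
  tab$delta_bic <- round(tab$delta_bic, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Winner: %s (BIC margin over runner-up: %.*f)\n",
              x$winner, digits, x$delta_bic))
  invisible(x)
}

#' @export
as.data.frame.info_model_comparison <- function(x, ...) x$table

#' Combined model with all three information-value regressors
#'
#' Fits a single logistic mixed model carrying the linear, entropy-reduction
#' and early-resolution Information Values as simultaneous regressors (plus
#' the subject random intercept), to ask which property of information best
#' predicts choice when the others are controlled. The three value vectors
#' are deterministic functions of the same six-level factor and are highly
#' correlated, so a collinearity warning reports the design-matrix
#' condition number when it is large.
#'
#' @inheritParams compare_info_models
#' @return A `choice_glmm` fit with regressors `v_linear`, `v_entropy`,
#'   `v_early`; per-regressor Wald z statistics are in `$coef_table`.
#' @examples
#' \donttest{
#' trials <- simulate_cohort(8, experiment = 1, seed = 3)
#' combined_info_model(trials)$coef_table
#' }
#' @export
combined_info_model <- function(data, nAGQ = 1) {
  data <- prepare_choice_data(data)
  data$v_linear <- info_value("linear", data$n_informative)
  data$v_entropy <- info_value("entropy_reduction", data$n_informative)
  data$v_early <- info_value("early_resolution", data$n_informative)
  X <- cbind(1, data$v_linear, data$v_entropy, data$v_early)
  cn <- kappa(crossprod(X), exact = TRUE)^0.5
  if (cn > 30) {
    warning(sprintf(paste("information-value regressors are highly",
                          "collinear (condition number %.1f)"), cn),
            call. = FALSE)
  }
  fit_choice_glmm(accept ~ v_linear + v_entropy + v_early + (1 | subject_id),
                  data, nAGQ = nAGQ)
}

#' Parametric bootstrap confidence interval for an information-value effect
#'
#' Goodness-of-fit check by parametric bootstrap: simulates `n_boot`
#' response vectors from the fitted model (new random intercepts drawn from
#' the estimated distribution), refits the model to each, and returns the
#' percentile interval of the Information-Value coefficient.
#'
#' @param fit A converged `choice_glmm` with a single `info_value`
#'   regressor (as produced inside [compare_info_models()]), or trial data
#'   plus `model_id` to fit one first.
#' @param model_id Information-value model id, used when `fit` is raw data.
#' @param n_boot Number of bootstrap replicates (the reference procedure
#'   uses 1,000).
#' @param level Confidence level; 0.99 gives the 0.5th/99.5th percentiles.
#' @param seed Optional seed for reproducibility.
#' @return List with `lower`, `upper`, `level`, `estimate` (the original
#'   coefficient), `estimates` (the bootstrap replicates) and `n_failed`
#'   (refits that failed; an error is raised if more than 10% fail).
#' @examples
#' \donttest{
#' trials <- simulate_cohort(6, experiment = 1, seed = 9)
#' bootstrap_coefficient_ci(trials, "early_resolution", n_boot = 20,
#'                          level = 0.9, seed = 1)
#' }
#' @export
bootstrap_coefficient_ci <- function(fit, model_id = "early_resolution",
                                     n_boot = 1000, level = 0.99,
                                     seed = NULL) {
  if (!inherits(fit, "choice_glmm")) {
    data <- prepare_choice_data(fit)
    data$info_value <- info_value(model_id, data$n_informative)
    fit <- fit_choice_glmm(accept ~ info_value + (1 | subject_id), data)
  }
  term <- setdiff(names(fit$coefficients), "(Intercept)")
  if (length(term) != 1L) {
    stop("fit must carry exactly one information-value regressor",
         call. = FALSE)
  }
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (n_boot < 1L) stop("n_boot must be at least 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sims <- simulate(fit$model, nsim = n_boot, use.u = FALSE)
  est <- vapply(seq_len(n_boot), function(b) {
    tryCatch(lme4::fixef(lme4::refit(fit$model, sims[[b]]))[[term]],
             error = function(e) NA_real_)
  }, numeric(1))
  n_failed <- sum(is.na(est))
  if (n_failed > 0.1 * n_boot) {
    stop(sprintf("%d of %d bootstrap refits failed", n_failed, n_boot),
         call. = FALSE)
  }
  alpha <- (1 - level) / 2
  qs <- quantile(est, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(lower = qs[1], upper = qs[2], level = level,
       estimate = unname(fit$coefficients[term]),
       estimates = est, n_failed = n_failed)
}

#' Sample size for a chi-square test of given power
#'
#' Smallest number of observations \eqn{N} for which a chi-square test with
#' `df` degrees of freedom, significance level `alpha` and Cohen's effect
#' size `w` reaches the target power, using the noncentral chi-square
#' distribution with noncentrality \eqn{\lambda = N w^2} and the central
#' chi-square critical value.
#'
#' @param w Cohen's w effect size (> 0).
#' @param df Degrees of freedom of the test (integer >= 1).
#' @param alpha Significance level, in (0, 1).
#' @param power Target power, in (0, 1).
#' @return The required sample size as an integer.
#' @examples
#' required_sample_size(w = 0.78, df = 5)            # 28
#' required_sample_size(w = 1.0, df = 1)             # 11
#' @export
required_sample_size <- function(w, df, alpha = 0.05, power = 0.9) {
  stopifnot(length(w) == 1L, length(df) == 1L)
  if (!is.finite(w) || w <= 0) stop("w must be positive", call. = FALSE)
  if (df < 1 || df != as.integer(df)) {
    stop("df must be a positive integer", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  }
  crit <- qchisq(1 - alpha, df)
  pow <- function(n) pchisq(crit, df, ncp = n * w^2, lower.tail = FALSE)
  hi <- 1
  while (pow(hi) < power) {
    hi <- hi * 2
    if (hi > 1e7) stop("target power unattainable", call. = FALSE)
  }
  lo <- 0
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2
    if (pow(mid) >= power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}
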