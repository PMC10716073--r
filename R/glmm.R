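#' Prepare trial records for model fitting
#'
#' Adds the derived columns the analysis models use: `accept` (0/1 response,
#' 1 = gamble accepted), `info_avail` (information availability as an
#' *ordered* factor with levels 0--5, so that its effect on gambling is not
#' assumed linear), `stake_f` (stake as an unordered factor) and `timing`
#' (relative-timing factor `EARLY`/`LATE`, `NA` where undefined).
#'
#' @param data Trial records with columns `choice`, `n_informative`,
#'   `stake_cents`, `arrangement` and `subject_id` (e.g. from
#'   [simulate_cohort()] or [read_trials()]).
#' @return `data` with the derived columns appended.
#' @examples
#' d <- prepare_choice_data(simulate_cohort(3, seed = 1))
#' levels(d$info_avail)
#' @export
prepare_choice_data <- function(data) {
  need <- c("choice", "n_informative", "stake_cents", "subject_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  data$accept <- as.integer(data$choice == "ACCEPT")
  data$info_avail <- factor(data$n_informative, levels = 0:5, ordered = TRUE)
  data$stake_f <- factor(data$stake_cents)
  data$timing <- if ("arrangement" %in% names(data)) {
    factor(data$arrangement, levels = c("EARLY", "LATE"))
  } else {
    factor(rep(NA_character_, nrow(data)), levels = c("EARLY", "LATE"))
  }
  data$subject_id <- factor(data$subject_id)
  data
}

#' Fit a logistic mixed model of gamble acceptance
#'
#' Fits a Bernoulli-logit mixed model with subject-specific random
#' intercepts by maximum likelihood, marginalizing the random intercept per
#' subject by adaptive Gauss--Hermite quadrature (`nAGQ = 1` is the Laplace
#' approximation). This is the workhorse behind every analysis in the
#' package: information availability as an ordinal factor, information
#' value as a continuous regressor, stake and timing factors all enter
#' through `formula`.
#'
#' @param formula Two-sided formula in lme4 notation with a binary response
#'   and exactly one random term, the subject intercept, e.g.
#'   `accept ~ info_avail + (1 | subject_id)`. A `choice` response coded
#'   `"ACCEPT"`/`"REJECT"` is converted automatically.
#' @param data Trial records; passed through [prepare_choice_data()] when
#'   the derived columns are absent.
#' @param nAGQ Number of adaptive Gauss--Hermite quadrature nodes (1 =
#'   Laplace). More nodes give a more accurate likelihood at some cost.
#' @param ... Passed to [lme4::glmer()].
#' @return An object of class `choice_glmm`: a list with the fitted
#'   [lme4::glmer()] model (`$model`), `coefficients` (fixed effects),
#'   `coef_table` (estimate, se, z, p), `sigma_b` (random-intercept SD on
#'   the log-odds scale), `loglik`, `n_obs`, `n_params` (fixed effects + 1
#'   variance component), `bic` (\eqn{-2\ell + k \log n}) and a `converged`
#'   flag. Never throws on non-convergence; inspect `converged`.
#' @seealso [wald_type2()], [marginal_means()], [pairwise_contrasts()],
#'   [compare_info_models()]
#' @examples
#' trials <- simulate_cohort(6, experiment = 1, seed = 42)
#' fit <- fit_choice_glmm(accept ~ info_avail + (1 | subject_id), trials)
#' fit
#' @export
fit_choice_glmm <- function(formula, data, nAGQ = 1, ...) {
  if (!"accept" %in% names(data) || !"info_avail" %in% names(data)) {
    data <- prepare_choice_data(data)
  }
  resp <- all.vars(formula)[1]
  if (resp == "choice") {
    formula <- stats::update(formula, accept ~ .)
  }
  if (length(unique(data$subject_id)) < 2L) {
    stop("at least two subjects are required", call. = FALSE)
  }
  msgs <- character(0)
  fit <- withCallingHandlers(
    lme4::glmer(formula, data = data, family = binomial(), nAGQ = nAGQ, ...),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
  converged <- fit@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", c(msgs, conv_msgs), ignore.case = TRUE))
  if (any(grepl("fitted probabilities|unable to evaluate scaled gradient",
                msgs))) {
    warning("possible separation or unstable fit; inspect coefficients",
            call. = FALSE)
  }
  ct <- stats::coef(summary(fit))
  colnames(ct) <- c("estimate", "se", "z", "p")
  ll <- as.numeric(logLik(fit))
  n_obs <- stats::nobs(fit)
  n_params <- length(lme4::fixef(fit)) + 1L
  structure(list(
    model = fit,
    formula = formula,
    data = data,
    coefficients = lme4::fixef(fit),
    coef_table = ct,
    sigma_b = sqrt(unname(lme4::VarCorr(fit)[[1]][1, 1])),
    loglik = ll,
    n_obs = n_obs,
    n_params = n_params,
    bic = -2 * ll + n_params * log(n_obs),
    nAGQ = nAGQ,
    converged = converged,
    messages = c(msgs, conv_msgs)
  ), class = "choice_glmm")
}

#' @export
print.choice_glmm <- function(x, digits = 4, ...) {
  cat("Logistic mixed model of gamble acceptance\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  n = %d trials, %d subjects; nAGQ = %d%s\n", x$n_obs,
              nlevels(x$data$subject_id), x$nAGQ,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("Fixed effects (log-odds):\n")
  print(round(x$coef_table, digits))
  cat(sprintf("Random intercept SD: %.*f\n", digits, x$sigma_b))
  cat(sprintf("logLik = %.2f, BIC = %.2f (k = %d)\n",
              x$loglik, x$bic, x$n_params))
  invisible(x)
}

#' @export
summary.choice_glmm <- function(object, ...) {
  structure(list(
    formula = object$formula,
    coef_table = object$coef_table,
    sigma_b = object$sigma_b,
    loglik = object$loglik,
    bic = object$bic,
    n_obs = object$n_obs,
    n_params = object$n_params,
    converged = object$converged
  ), class = "summary.choice_glmm")
}

#' @export
print.summary.choice_glmm <- function(x, ...) {
  cat("Call: ", deparse(x$formula), "\n", sep = "")
  print(x$coef_table)
  cat(sprintf("sigma_b = %.4f | logLik = %.3f | BIC = %.3f | n = %d | %s\n",
              x$sigma_b, x$loglik, x$bic, x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.choice_glmm <- function(object, ...) object$coefficients

#' @export
vcov.choice_glmm <- function(object, ...) as.matrix(vcov(object$model))

#' @export
logLik.choice_glmm <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' Predicted acceptance probabilities
#'
#' @param object A `choice_glmm` fit.
#' @param newdata Optional trial records; defaults to the fitting data.
#' @param type `"response"` (probability) or `"link"` (log-odds).
#' @param re.form Random-effects specification as in
#'   [lme4::predict.merMod()]; the default `NA` predicts for a typical
#'   subject (random intercept 0).
#' @param ... Passed to [lme4::predict.merMod()].
#' @return Numeric vector of predictions.
#' @export
predict.choice_glmm <- function(object, newdata = NULL,
                                type = c("response", "link"),
                                re.form = NA, ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    predict(object$model, type = type, re.form = re.form, ...)
  } else {
    if (!"accept" %in% names(newdata)) newdata <- prepare_choice_data(newdata)
    predict(object$model, newdata = newdata, type = type,
            re.form = re.form, ...)
  }
}

#' Simulate responses from a fitted model
#'
#' Parametric simulation of accept/reject responses from the fitted model,
#' drawing fresh subject intercepts from the estimated random-effect
#' distribution (`use.u = FALSE`), as used by the parametric bootstrap.
#'
#' @param object A `choice_glmm` fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Passed to [lme4::simulate.merMod()].
#' @return A data.frame with `nsim` columns of simulated 0/1 responses.
#' @export
simulate.choice_glmm <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$model, nsim = nsim, seed = seed, use.u = FALSE, ...)
}

#' @export
residuals.choice_glmm <- function(object, type = "deviance", ...) {
  residuals(object$model, type = type, ...)
}

#' @export
fitted.choice_glmm <- function(object, ...) fitted(object$model, ...)

#' Observed vs fitted acceptance by information availability
#'
#' Plots the observed mean acceptance rate at each level of information
#' availability together with the model's population-level prediction
#' (random intercept at zero), a quick goodness-of-fit diagnostic.
#'
#' @param x A `choice_glmm` fit whose data contain `info_avail`.
#' @param ... Passed to [plot()].
#' @return Invisibly, the data.frame of observed and fitted means.
#' @export
plot.choice_glmm <- function(x, ...) {
  d <- x$data
  obs <- aggregate(accept ~ info_avail, data = d, FUN = mean)
  d$.fit <- predict(x, type = "response")
  fit <- aggregate(.fit ~ info_avail, data = d, FUN = mean)
  lv <- as.integer(as.character(obs$info_avail))
  plot(lv, obs$accept, ylim = c(0, 1), pch = 19,
       xlab = "Informative windows", ylab = "Pr(accept)", ...)
  lines(as.integer(as.character(fit$info_avail)), fit$.fit, type = "b",
        pch = 1, lty = 2)
  graphics::legend("bottomright", legend = c("observed", "fitted"),
                   pch = c(19, 1), lty = c(NA, 2), bty = "n")
  invisible(data.frame(info_avail = obs$info_avail, observed = obs$accept,
                       fitted = fit$.fit))
}

#' Type II Wald chi-square tests
#'
#' Tests each fixed factor's coefficient block with a Wald chi-square
#' statistic using the estimated fixed-effect covariance, with Type II
#' marginality (each term tested after the other terms of equal or lower
#' order). The degrees of freedom equal the number of coefficients in the
#' block: 5 for the six-level information-availability factor.
#'
#' @param fit A `choice_glmm` object.
#' @param term Optional term name; if supplied, returns that term's
#'   statistics as a list with `chi2`, `df` and `p`.
#' @return With `term = NULL`, a data.frame with one row per fixed term
#'   (`term`, `chi2`, `df`, `p`); otherwise a list for the given term.
#' @examples
#' trials <- simulate_cohort(6, experiment = 1, seed = 42)
#' fit <- fit_choice_glmm(accept ~ info_avail + (1 | subject_id), trials)
#' wald_type2(fit, "info_avail")
#' @export
wald_type2 <- function(fit, term = NULL) {
  stopifnot(inherits(fit, "choice_glmm"))
  an <- car::Anova(fit$model, type = "II", test.statistic = "Chisq")
  out <- data.frame(term = rownames(an), chi2 = an$Chisq, df = an$Df,
                    p = an[["Pr(>Chisq)"]], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (is.null(term)) return(out)
  row <- out[out$term == term, ]
  if (nrow(row) == 0L) {
    stop("term '", term, "' is not a fixed factor of the model",
         call. = FALSE)
  }
  list(chi2 = row$chi2, df = row$df, p = row$p)
}

emm_of <- function(fit, factor) {
  stopifnot(inherits(fit, "choice_glmm"))
  if (!factor %in% all.vars(fit$formula)) {
    stop("factor '", factor, "' is not in the model", call. = FALSE)
  }
  emmeans::emmeans(fit$model, specs = factor, data = fit$data)
}

#' Marginal mean acceptance rates
#'
#' Estimated marginal means for a fixed factor: the linear predictor is
#' averaged over the other factors' levels with the random intercept at its
#' population mean of zero, then inverse-logit transformed to the
#' probability scale.
#'
#' @param fit A converged `choice_glmm` object.
#' @param factor Name of a fixed factor in the model.
#' @return A data.frame with one row per level: `level`, `prob` (marginal
#'   mean acceptance rate), `se`, `asymp_lcl`, `asymp_ucl`.
#' @examples
#' trials <- simulate_cohort(6, experiment = 1, seed = 42)
#' fit <- fit_choice_glmm(accept ~ info_avail + (1 | subject_id), trials)
#' marginal_means(fit, "info_avail")
#' @export
marginal_means <- function(fit, factor) {
  em <- as.data.frame(summary(emm_of(fit, factor), type = "response"))
  data.frame(level = as.character(em[[1]]), prob = em$prob, se = em$SE,
             asymp_lcl = em$asymp.LCL, asymp_ucl = em$asymp.UCL,
             stringsAsFactors = FALSE)
}

#' Holm-adjusted pairwise contrasts
#'
#' All pairwise contrasts between a factor's levels on the log-odds scale
#' (15 pairs for the six levels of information availability), with
#' asymptotic z statistics and Holm step-down adjustment of the p-values
#' over the full family.
#'
#' @inheritParams marginal_means
#' @return A data.frame with one row per pair: `level_a`, `level_b`,
#'   `estimate` (log-odds difference a - b), `se`, `z`, `p_raw`, `p_holm`.
#' @examples
#' trials <- simulate_cohort(6, experiment = 1, seed = 42)
#' fit <- fit_choice_glmm(accept ~ info_avail + (1 | subject_id), trials)
#' head(pairwise_contrasts(fit, "info_avail"))
#' @export
pairwise_contrasts <- function(fit, factor) {
  pr <- as.data.frame(summary(emmeans::contrast(emm_of(fit, factor),
                                                method = "pairwise",
                                                adjust = "none")))
  levels_ab <- strsplit(as.character(pr$contrast), " - ", fixed = TRUE)
  clean <- function(x) gsub("^\\(|\\)$|^\\s+|\\s+$", "", x)
  out <- data.frame(
    level_a = clean(vapply(levels_ab, `[`, "", 1L)),
    level_b = clean(vapply(levels_ab, `[`, "", 2L)),
    estimate = pr$estimate,
    se = pr$SE,
    z = pr$z.ratio,
    p_raw = pr$p.value,
    stringsAsFactors = FALSE
  )
  # strip the factor name prefix emmeans adds to ordered-factor levels
  fpref <- paste0("^", factor)
  out$level_a <- sub(fpref, "", out$level_a)
  out$level_b <- sub(fpref, "", out$level_b)
  out$p_holm <- p.adjust(out$p_raw, method = "holm")
  out
}
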