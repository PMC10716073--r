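#' Run the full analysis pipeline on trial records
#'
#' Reproduces the study's inferential pipeline on a trial-level dataset:
#' \enumerate{
#'   \item Per experiment, a logistic mixed model of choice with
#'     information availability as an ordered factor (plus stake as a
#'     factor and their interaction when more than one stake is present),
#'     with Type II Wald chi-square tests, marginal mean acceptance rates
#'     and Holm-adjusted pairwise contrasts for each fixed factor.
#'   \item For experiment 3, an additional relative-timing analysis
#'     restricted to 1--4 informative windows — the subset in which early
#'     and late placement of the informative windows can be compared
#'     directly.
#'   \item On the pooled data, the four-model information-value comparison
#'     by BIC and the combined model with all three value regressors.
#' }
#'
#' @param data Trial records (multiple experiments may be mixed; the
#'   `experiment` column splits them).
#' @param nAGQ Quadrature nodes for all fits.
#' @return An object of class `infolottery_analysis`: list with
#'   `per_experiment` (for each experiment: `fit`, `wald`,
#'   `marginal_means`, `contrasts`, and for experiment 3 `timing_fit`,
#'   `timing_wald`), `comparison` (an `info_model_comparison`) and
#'   `combined` (a `choice_glmm`).
#' @examples
#' \donttest{
#' trials <- simulate_cohort(6, experiment = 1, seed = 11)
#' analyze_trials(trials)
#' }
#' @export
analyze_trials <- function(data, nAGQ = 1) {
  data <- prepare_choice_data(data)
  per_exp <- lapply(split(data, data$experiment), function(d) {
    multi_stake <- length(unique(d$stake_cents)) > 1L
    fm <- if (multi_stake) {
      accept ~ info_avail * stake_f + (1 | subject_id)
    } else {
      accept ~ info_avail + (1 | subject_id)
    }
    fit <- fit_choice_glmm(fm, d, nAGQ = nAGQ)
    res <- list(
      fit = fit,
      wald = wald_type2(fit),
      marginal_means = marginal_means(fit, "info_avail"),
      contrasts = pairwise_contrasts(fit, "info_avail")
    )
    if (any(!is.na(d$timing))) {
      sub <- d[!is.na(d$timing), ]
      sub$info_avail <- droplevels(sub$info_avail)
      tfm <- if (multi_stake) {
        accept ~ info_avail + timing + stake_f + (1 | subject_id)
      } else {
        accept ~ info_avail + timing + (1 | subject_id)
      }
      res$timing_fit <- fit_choice_glmm(tfm, sub, nAGQ = nAGQ)
      res$timing_wald <- wald_type2(res$timing_fit)
    }
    res
  })
  structure(list(
    per_experiment = per_exp,
    comparison = compare_info_models(data, nAGQ = nAGQ),
    combined = suppressWarnings(combined_info_model(data, nAGQ = nAGQ))
  ), class = "infolottery_analysis")
}

#' @export
print.infolottery_analysis <- function(x, ...) {
  for (e in names(x$per_experiment)) {
    cat("== Experiment ", e, " ==\n", sep = "")
    print(x$per_experiment[[e]]$wald, row.names = FALSE)
    if (!is.null(x$per_experiment[[e]]$timing_wald)) {
      cat("-- relative timing (1-4 informative windows) --\n")
      print(x$per_experiment[[e]]$timing_wald, row.names = FALSE)
    }
  }
  cat("== Pooled model comparison ==\n")
  print(x$comparison)
  invisible(x)
}

#' Write analysis reports to a directory
#'
#' Exports the results of [analyze_trials()] as plain-text artifacts: per
#' experiment a fit-summary CSV (`term, estimate, se, z, p`), marginal
#' means and contrast CSVs; the pooled comparison CSV
#' (`model_id, n_params, loglik, bic, delta_bic, converged`); and a JSON
#' manifest with fit statistics and convergence diagnostics.
#'
#' @param analysis An `infolottery_analysis` object.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
write_analysis_reports <- function(analysis, dir) {
  stopifnot(inherits(analysis, "infolottery_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(dir, name)
    utils::write.csv(obj, p, row.names = FALSE, fileEncoding = "UTF-8")
    paths <<- c(paths, p)
  }
  coefs_df <- function(fit) {
    data.frame(term = rownames(fit$coef_table), fit$coef_table,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  for (e in names(analysis$per_experiment)) {
    res <- analysis$per_experiment[[e]]
    wr(coefs_df(res$fit), sprintf("exp%s_fit.csv", e))
    wr(res$wald, sprintf("exp%s_wald.csv", e))
    wr(res$marginal_means, sprintf("exp%s_marginal_means.csv", e))
    wr(res$contrasts, sprintf("exp%s_contrasts.csv", e))
    if (!is.null(res$timing_wald)) {
      wr(res$timing_wald, sprintf("exp%s_timing_wald.csv", e))
    }
  }
  wr(analysis$comparison$table, "model_comparison.csv")
  wr(coefs_df(analysis$combined), "combined_model.csv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(
      winner = analysis$comparison$winner,
      delta_bic = analysis$comparison$delta_bic,
      fits = lapply(analysis$per_experiment, function(res) {
        list(formula = deparse(res$fit$formula), loglik = res$fit$loglik,
             bic = res$fit$bic, n_obs = res$fit$n_obs,
             sigma_b = res$fit$sigma_b, converged = res$fit$converged)
      })
    )
    p <- file.path(dir, "manifest.json")
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
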