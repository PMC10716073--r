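# one moderate fit shared across blocks
fit_exp1 <- local({
  trials <- tiny_cohort(8, seed = 42)
  fit_choice_glmm(accept ~ info_avail + (1 | subject_id), trials)
})

test_that("zero-variance cohorts reduce to the ordinary logistic oracle", {
  # under a common intercept the ML variance estimate either hits the zero
  # boundary -- where the mixed fit must coincide with plain logistic
  # regression -- or picks up a small spurious heterogeneity that moves the
  # fixed effects only marginally
  boundary_seen <- FALSE
  for (s in 101:106) {
    trials <- simulate_cohort(28, experiment = 1, sigma = 0, mu = 0.3,
                              beta_info = 1.2, seed = s)
    trials <- prepare_choice_data(trials)
    trials$info_value <- info_value("early_resolution", trials$n_informative)
    fit <- suppressMessages(
      fit_choice_glmm(accept ~ info_value + (1 | subject_id), trials))
    oracle <- glm(accept ~ info_value, family = binomial(), data = trials)
    gap <- max(abs(coef(fit) - coef(oracle)))
    expect_lt(fit$sigma_b, 0.15)
    expect_lt(gap, 5e-3)
    if (fit$sigma_b < 1e-6) {
      boundary_seen <- TRUE
      expect_lt(gap, 1e-4)
    }
  }
  expect_true(boundary_seen)
})

test_that("fit metadata satisfies the BIC identity and convergence contract", {
  expect_s3_class(fit_exp1, "choice_glmm")
  expect_true(fit_exp1$converged)
  expect_equal(fit_exp1$bic,
               -2 * fit_exp1$loglik + fit_exp1$n_params * log(fit_exp1$n_obs))
  expect_equal(fit_exp1$bic, BIC(fit_exp1$model), tolerance = 1e-8)
  expect_equal(fit_exp1$n_params, 7L)  # 6 fixed effects + 1 variance
  expect_equal(fit_exp1$n_obs, 8L * 180L)
  expect_error(
    fit_choice_glmm(accept ~ info_avail + (1 | subject_id),
                    tiny_cohort(1, seed = 1)),
    "two subjects")
})

test_that("adding a regressor never decreases the log-likelihood", {
  trials <- prepare_choice_data(tiny_cohort(6, experiment = 2, seed = 77))
  trials$info_value <- info_value("linear", trials$n_informative)
  f0 <- fit_choice_glmm(accept ~ 1 + (1 | subject_id), trials)
  f1 <- fit_choice_glmm(accept ~ info_value + (1 | subject_id), trials)
  f2 <- fit_choice_glmm(accept ~ info_value + stake_f + (1 | subject_id),
                        trials)
  expect_gte(f1$loglik, f0$loglik)
  expect_gte(f2$loglik, f1$loglik)
})

test_that("estimates are stable in the number of quadrature nodes", {
  trials <- prepare_choice_data(tiny_cohort(8, seed = 55))
  trials$info_value <- info_value("early_resolution", trials$n_informative)
  f9 <- fit_choice_glmm(accept ~ info_value + (1 | subject_id), trials,
                        nAGQ = 9)
  f15 <- fit_choice_glmm(accept ~ info_value + (1 | subject_id), trials,
                         nAGQ = 15)
  expect_lt(max(abs(coef(f9) - coef(f15))), 1e-3)
  expect_lt(abs(f9$sigma_b - f15$sigma_b), 1e-3)
})

test_that("Type II Wald tests carry the factor's block degrees of freedom", {
  w <- wald_type2(fit_exp1, "info_avail")
  expect_equal(w$df, 5)
  expect_true(w$chi2 > 0 && w$p >= 0 && w$p <= 1)
  expect_error(wald_type2(fit_exp1, "stake_f"), "not a fixed factor")

  # a single binary factor's chi-square is the square of its z statistic
  trials <- prepare_choice_data(tiny_cohort(6, experiment = 3, seed = 17))
  sub <- trials[!is.na(trials$timing), ]
  fit <- fit_choice_glmm(accept ~ timing + (1 | subject_id), sub)
  w1 <- wald_type2(fit, "timing")
  expect_equal(w1$df, 1)
  expect_equal(w1$chi2, unname(fit$coef_table["timingLATE", "z"]^2),
               tolerance = 1e-6)
})

test_that("marginal means invert the per-level linear predictor", {
  mm <- marginal_means(fit_exp1, "info_avail")
  expect_equal(mm$level, as.character(0:5))
  expect_true(all(mm$prob > 0 & mm$prob < 1))
  newd <- data.frame(info_avail = factor(0:5, levels = 0:5, ordered = TRUE),
                     subject_id = fit_exp1$data$subject_id[1])
  direct <- predict(fit_exp1$model, newdata = newd, re.form = NA,
                    type = "response")
  expect_equal(mm$prob, unname(direct), tolerance = 1e-6)
  expect_error(marginal_means(fit_exp1, "stake_f"), "not in the model")
})

test_that("pairwise contrasts form the full Holm-adjusted family", {
  pc <- pairwise_contrasts(fit_exp1, "info_avail")
  expect_equal(nrow(pc), choose(6, 2))
  expect_true(all(pc$p_holm >= pc$p_raw - 1e-12))
  expect_true(all(pc$p_holm <= 1))
  # step-down monotonicity: sorted by raw p, adjusted p is non-decreasing
  ord <- order(pc$p_raw)
  expect_true(all(diff(pc$p_holm[ord]) >= -1e-12))
  expect_setequal(unique(c(pc$level_a, pc$level_b)), as.character(0:5))
  # contrast estimates match the marginal means on the logit scale
  mm <- marginal_means(fit_exp1, "info_avail")
  lp <- qlogis(mm$prob)
  expect_equal(pc$estimate[pc$level_a == "0" & pc$level_b == "5"],
               lp[1] - lp[6], tolerance = 1e-6)
})

test_that("choice_glmm methods expose the fit coherently", {
  expect_output(print(fit_exp1), "Logistic mixed model")
  s <- summary(fit_exp1)
  expect_s3_class(s, "summary.choice_glmm")
  expect_equal(nrow(s$coef_table), 6)
  expect_length(predict(fit_exp1), fit_exp1$n_obs)
  pr <- predict(fit_exp1, type = "response")
  expect_true(all(pr > 0 & pr < 1))
  sim <- simulate(fit_exp1, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(fit_exp1$n_obs, 2L))
  expect_length(residuals(fit_exp1), fit_exp1$n_obs)
  expect_equal(as.numeric(logLik(fit_exp1)), fit_exp1$loglik)
  expect_equal(dim(vcov(fit_exp1)), c(6L, 6L))
})

test_that("recovered effects track the generative parameters", {
  # moderate single-replicate recovery; the full 50-replicate study-scale
  # recovery lives with the acceptance checks
  trials <- prepare_choice_data(
    simulate_cohort(20, experiment = 1, beta_info = 1.2, sigma = 0.8,
                    seed = 301))
  trials$info_value <- info_value("early_resolution", trials$n_informative)
  fit <- fit_choice_glmm(accept ~ info_value + (1 | subject_id), trials)
  expect_lt(abs(unname(coef(fit)["info_value"]) - 1.2), 0.5)
  expect_lt(abs(fit$sigma_b - 0.8), 0.5)
})
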