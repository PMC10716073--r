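# infolottery

Modelling how **non-instrumental information** — advance previews of a
lottery outcome that cannot change it — alters the willingness to gamble.

The setting is a five-window slot machine: a lottery of five faces, each
independently winning with probability 0.5, pays out on a majority (≥ 3)
of winning faces. Before choosing whether to stake money on the lottery,
the player learns which windows are *informative*; after an accepted
gamble those windows reveal veridical faces from the final sequence, the
others show random faces. The information arrives after the decision and
has no instrumental value, yet it changes choice. The package implements
the full computational pipeline for asking *which property of the
information* drives that change.

## What is inside

**Four information-value models.** Each maps the number of informative
windows *i* ∈ {0,…,5} to a value V(i) that enters a logistic model of
choice:

- *baseline* — V(i) = 0;
- *linear* — V(i) = i/5;
- *entropy reduction* — the expected drop in Shannon entropy of the win
  probability after seeing the informative windows, averaged over all 2^i
  equiprobable permutations of revealed faces, using the binomial tail
  P(win | i, w_min) = Σ_{k=w_min}^{5−i} C(5−i, k) 0.5^(5−i) for each
  permutation (w_min = additional winning faces needed for a majority);
- *early resolution* — the probability that the revealed faces alone fix
  the outcome: P(early | i) = Σ_{k=3}^{i} C(i, k) 0.5^(i−1) for i ≥ 3,
  else 0.

`info_value_table()` reproduces the canonical 4 × 6 value table
(entropy reduction: 0, 0.104, 0.228, 0.392, 0.625, 1; early resolution:
0, 0, 0, 0.25, 0.625, 1), and both non-trivial rows are verified against
brute-force permutation enumeration in the test suite.

**A generative simulator** (`build_design()`, `simulate_lottery()`,
`simulate_choices()`, `simulate_cohort()`) of the three experimental
designs — 180 trials per subject; six information levels; five stakes
(10–50 ¢) in experiments 2–3; early/late placement of informative windows
in experiment 3 — with subject-specific gamble propensities drawn from a
normal population on the log-odds scale.

**Mixed-logistic inference** (`fit_choice_glmm()` returning a classed fit
with `print`, `summary`, `coef`, `predict`, `simulate`, `residuals` and
`plot` methods; `wald_type2()`, `marginal_means()`,
`pairwise_contrasts()`): subject random intercepts, adaptive
Gauss–Hermite quadrature, Type II Wald chi-square tests, marginal mean
acceptance rates, Holm-adjusted pairwise contrasts.

**Model comparison and power** (`compare_info_models()`,
`combined_info_model()`, `bootstrap_coefficient_ci()`,
`required_sample_size()`): BIC ranking of the four models, the combined
three-regressor model, parametric bootstrap confidence intervals, and
noncentral chi-square sample-size computation for Cohen's w
(λ = N·w²).

## Worked example

```r
library(infolottery)

trials <- simulate_cohort(22, experiment = 1, seed = 2024)  # 22 x 180 trials
fit <- fit_choice_glmm(accept ~ info_avail + (1 | subject_id), trials)

wald_type2(fit, "info_avail")
#> $chi2              # effect of information availability on choice
#> [1] 126.2233
#> $df
#> [1] 5
#> $p
#> [1] 1.505811e-25

marginal_means(fit, "info_avail")[, 1:2]
#>   level      prob        # acceptance rises with informative windows
#> 1     0 0.4610412
#> 2     1 0.4700030
#> 3     2 0.4771911
#> 4     3 0.5242434
#> 5     4 0.6336097
#> 6     5 0.7264360

compare_info_models(trials)
#> Information-value model comparison (4 models, n = 3960 trials)
#>           model_id n_params   loglik     bic converged delta_bic
#>           baseline        2 -2429.04 4874.64      TRUE    124.83
#>             linear        3 -2373.14 4771.12      TRUE     21.31
#>  entropy_reduction        3 -2364.86 4754.56      TRUE      4.75
#>   early_resolution        3 -2362.48 4749.82      TRUE      0.00
#> Winner: early_resolution (BIC margin over runner-up: 4.75)

required_sample_size(w = 0.78, df = 5, alpha = 0.05, power = 0.9)
#> [1] 28
```

The simulated cohort was generated under the early-resolution model
(`beta_info = 1.2`), and the BIC comparison recovers it: the
early-resolution fit beats the entropy-reduction runner-up by 4.7 BIC
units, and all three value models beat the intercept-only baseline. The
Wald test has 5 df (six information levels), and the marginal means show
acceptance climbing mainly between two and five informative windows —
the signature pattern of valuing early resolution of uncertainty.

A command-line wrapper over the same functions ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/infolottery.R", package="infolottery"))')" \
    simulate --experiment 1 --subjects 22 --seed 1 --out trials.csv
```

with subcommands `table1`, `simulate`, `analyze`, `compare`, `power`.

## Package layout

- `R/info_value.R` — the four value models and their enumeration machinery
- `R/synthetic_data.R` — designs, lotteries, generative choice simulation
- `R/glmm.R` — `choice_glmm` fits and the inferential toolkit
- `R/model_comparison.R` — BIC comparison, bootstrap, power
- `R/io.R`, `R/analyze.R` — trial CSV schema, config files, end-to-end
  pipeline and report writers
- `vignettes/information-value-models.Rmd` — models, assumptions,
  numerical choices and limitations
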