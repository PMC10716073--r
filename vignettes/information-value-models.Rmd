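---
title: "Information-value models of risky choice: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-value models of risky choice: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infolottery)
```

## The task and the question

A five-window slot machine plays a lottery of five faces, each independently
a winning or losing face with probability 0.5; the lottery pays out when at
least three faces win (with five faces a strict majority always exists).
Before deciding whether to gamble a stake on the lottery, the player is told
which windows are *informative*: after an accepted gamble those windows
reveal veridical faces from the final sequence, while the remaining windows
show independent random faces. Crucially the information is
non-instrumental -- it arrives after the decision and cannot change the
outcome or any future decision. The question the package's machinery
addresses is *which property of such information* makes people more (or
less) willing to gamble: its mere amount, its capacity to incrementally
reduce uncertainty, or its capacity to settle the outcome early.

## The four information-value models

Each model maps the number of informative windows
$i \in \{0, \dots, 5\}$ to a dimensionless "Information Value" that then
enters a logistic mixed model of choice as a continuous regressor.

**Baseline.** $V(i) = 0$: choice depends only on the subject's propensity
to gamble.

**Linear.** $V(i) = i/5$: value grows in equal steps of 0.2 with each
informative window.

**Entropy reduction.** The prior win probability is 0.5, so the prior
Shannon entropy is $H(0.5) = 1$ bit. For a revealed permutation with
$w$ winning faces among $i$ informative windows, the posterior win
probability is the binomial tail over the $r = 5 - i$ unrevealed windows,

$$P(\mathrm{win} \mid i, w_{\min}) =
  \sum_{k = w_{\min}}^{r} \binom{r}{k} 0.5^{r},$$

where $w_{\min} = \max(0, 3 - w)$ is the minimum number of additional
winning faces needed for a majority, and $P(\mathrm{win}) = 0$ when three
losing faces are already revealed (no $w_{\min}$ exists). The information
content of the permutation is $I = 1 - H(P(\mathrm{win}))$ with
$H(p) = -[p\log_2 p + (1-p)\log_2(1-p)]$ and $H(0) = H(1) = 0$, and the
model's value is the mean of $I$ over all $2^i$ permutations. All $2^i$
permutations are weighted equally: each informative window is an
independent fair draw, so uniform weighting is the only choice consistent
with the 50% prior. The win probability depends on the revealed faces only
through their counts, never through window positions; the implementation
exploits this (binomial weights over win counts) and the test suite checks
it against a position-aware enumeration oracle.

**Early resolution.** The probability that the informative windows alone
fix the outcome -- that the revealed permutation already contains at least
three winning or at least three losing faces:

$$P(\mathrm{early} \mid i) =
  \begin{cases}
    \sum_{k=3}^{i} \binom{i}{k}\, 0.5^{\,i-1} & i \ge 3 \\
    0 & i < 3,
  \end{cases}$$

the exponent $i - 1$ rather than $i$ counting both valences at once. For
$i = 3$ only the all-winning and all-losing permutations qualify, giving
$2/8 = 0.25$.

`info_value_table()` tabulates all four models:

```{r table}
tab <- info_value_table(digits = 3)
reshape(tab, idvar = "model_id", timevar = "n_informative",
        direction = "wide")
```

Values are reported at three decimals, which is the precision at which the
entropy-reduction cells (0.104, 0.228, 0.392, 0.625) are conventionally
printed; internally everything is kept in double precision, and the
enumeration oracle agreement is asserted to 1e-12. Both non-trivial value
sequences are non-decreasing in $i$ and reach 1 at $i = 5$; they tie at
$i = 4$ (0.625), so no ordering between the two models is asserted there.

## The synthetic-data generator

No trial-level human data are deposited with the study this design
follows, so the package ships a generative simulator whose defaults *are*
the study's conditions; the simulator is first-class, tested code, not a
fixture.

**Designs** (`build_design()`). Each subject completes 180 trials.
Experiment 1 crosses six information levels (30 trials each) at a fixed
50-cent stake. Experiment 2 crosses the six levels with five stakes
(10--50 cents), six trials per cell. Experiment 3 manipulates the relative
timing of information: for 1--4 informative windows the informative
windows form either a prefix (`EARLY`) or a suffix (`LATE`) of the five
positions (positions are 1-based, left to right). Window masks in
experiments 1 and 2 are drawn uniformly from all $\binom{5}{i}$
arrangements; for two and three informative windows that pool has exactly
10 members, so the "10 preselected arrangements" of the original design
are necessarily the complete set.

The split of experiment 3's 180 trials across timing and stake cells is
not fully determined by the published design; the generator adopts 18
trials in each of the ten (information x timing) cells, with stakes cycled
so that each stake occurs exactly 36 times overall and 3--4 times per
cell. This is a documented choice, not a reconstruction.

**Lotteries** (`simulate_lottery()`). The five faces are independent fair
draws, so the win rate is exactly 0.5 at every information level --
informative windows change what the player *knows*, never the odds. The
test suite checks outcome independence from the mask by a chi-square test
on 100,000 simulated trials.

**Choices** (`simulate_choices()`, `simulate_cohort()`). The generative
choice model mirrors the analysis model:

$$P(\mathrm{accept}) = \mathrm{logit}^{-1}\!\big(\alpha_s +
  \beta_{\mathrm{info}} V(i) + \beta_{\mathrm{stake}}(\mathrm{stake}-30)\big),
  \qquad \alpha_s \sim N(\mu, \sigma^2).$$

Stakes are centered at 30 cents so that $\mu$ is the population log-odds
of gambling at the mean stake. The defaults --
`model = "early_resolution"`, `beta_info = 1.2`, `beta_stake = -0.02`
per cent, `mu = 0.4`, `sigma = 0.8` -- were fixed once, on these grounds:
a baseline acceptance of $\mathrm{logit}^{-1}(0.4) \approx 0.60$ and a
full-information acceptance of $\mathrm{logit}^{-1}(1.6) \approx 0.83$
bracket the acceptance rates the study reports (roughly 0.6 to 0.8 across
information levels); `beta_info = 1.2` sits inside the bootstrap interval
the study prints for the early-resolution coefficient; the stake slope
spans 0.8 log-odds over the 40-cent range, reproducing the reported
risk-averse stake gradient; and `sigma = 0.8` gives the substantial
between-subject spread visible in the study's per-subject means. Default
cohort sizes are the study's: 22, 29 and 20 subjects for experiments 1--3.

What the simulator does *not* emulate: reaction times, missed responses
(0.3--0.6% of real trials, excluded from the study's choice models),
session-level endowment bookkeeping, engagement drift, and any systematic
deviation from the logistic functional form. Passing recovery tests
therefore show that the pipeline is correct and well calibrated *under its
own assumptions*; they cannot show that real choices follow the logistic
model.

## The mixed-model machinery

`fit_choice_glmm()` fits the Bernoulli-logit mixed model with a
subject-specific random intercept by maximum likelihood via
`lme4::glmer`, marginalizing the intercept with adaptive Gauss--Hermite
quadrature (`nAGQ = 1`, the Laplace approximation, is the default; the
suite checks that estimates move by less than 1e-3 between 9 and 15
nodes). Information availability enters as an *ordered* factor so that
its effect is not assumed linear; R's orthogonal polynomial contrasts are
used, and since any full-rank contrast basis yields the same block test,
nothing downstream depends on that basis. Stake enters as an unordered
factor (per-level marginal means are the quantity of interest);
a centered-continuous coding remains available through the formula
interface.

Inference follows the reference pipeline: Type II Wald chi-square tests
on fixed-factor coefficient blocks (`wald_type2()`, via `car::Anova`; df
equals the block size, 5 for the six-level information factor), marginal
mean acceptance rates with the random intercept at its population mean of
zero (`marginal_means()`, via `emmeans`), and all pairwise contrasts on
the log-odds scale with Holm step-down adjustment over the full family
(`pairwise_contrasts()`; 15 pairs for six levels).

Numerical notes. The fit never throws on non-convergence: the `converged`
flag records the optimizer status and lme4's convergence diagnostics, and
suspected separation is surfaced as a warning while the (finite,
penalized-by-nothing) estimates are returned for inspection. BIC is
$-2\ell + k\log n$ with $k$ = fixed effects + 1 variance component and
$n$ the number of *trial-level observations* -- the convention that
matches the magnitude of the published model-comparison table given its
12,780 pooled trials. When the generative intercept variance is zero, the
ML variance estimate lands on the zero boundary on a fraction of datasets
and the fixed effects then coincide with plain logistic regression to
machine precision; on the remaining datasets a small positive variance
estimate is the true MLE and the fixed effects differ from the GLM's by
a correspondingly small amount. The test suite asserts exactly this
two-case behaviour.

## Model comparison, bootstrap, power

`compare_info_models()` attaches each model's Information Value to every
trial, fits `accept ~ info_value + (1 | subject_id)` (the baseline model
reduces to the intercept-only mixed model), and ranks the four fits by
BIC; the winner's margin over the runner-up is reported. Because the
value regressor enters linearly with an intercept present, the BIC
ranking is invariant to affine rescaling of a value column -- the
coefficient absorbs the scale and the likelihood is unchanged -- which
the suite verifies. `combined_info_model()` carries the three non-trivial
value vectors simultaneously; they are deterministic functions of the
same six-level factor and hence highly collinear, so the fit warns with
the design-matrix condition number and per-regressor Wald z statistics
should be read with that in mind.

`bootstrap_coefficient_ci()` is a *parametric* bootstrap: response
vectors are simulated from the fitted model with fresh random intercepts
drawn from the estimated distribution, the model is refit to each
(via `lme4::refit`, which reuses the factorization), and the percentile
interval of the information-value coefficient is returned. Parametric
resampling was chosen over case resampling because the procedure being
mirrored is described as bootstrapped *simulations* and because subjects,
the natural resampling unit, number only in the tens. Failed refits are
skipped and counted; more than 10% failures is an error.

`required_sample_size()` inverts the noncentral chi-square power
function: with Cohen's effect size $w$, noncentrality $\lambda = N w^2$
and the central chi-square critical value at $1 - \alpha$, it returns the
smallest integer $N$ whose power reaches the target. For $w = 0.78$,
$\mathrm{df} = 5$, $\alpha = .05$, power $= .9$ this gives $N = 28$
(power 0.911; $N = 27$ gives 0.899). The published sample-size claim of
19 for the third experiment, stated as following from effect sizes 0.78
and 1.16, is not reproducible from any single $(w, \mathrm{df})$ pair
under this convention ($w = 1.16$, $\mathrm{df} = 5$ gives 13); the
derivation is ambiguous and the package documents rather than asserts it.

## Scale of the verification suites

The test suite verifies the stochastic machinery at sizes chosen to keep
a full run in ordinary desktop time while leaving comfortable Monte Carlo
margins: parameter recovery and model selection at the study scale
(50 cohorts of 30 subjects x 180 trials; the generating early-resolution
model must win the BIC comparison in at least 80% of cohorts and the mean
recovered coefficient must sit within 0.25 of the generative 1.2); null
calibration of the Wald test on 500 cohorts of 8 subjects (rejection rate
0.05 +/- 0.02, KS uniformity of p-values); bootstrap coverage at 10 outer
cohorts x 100 inner refits (a 99% interval must cover the generating
coefficient in at least 8 of 10); and a model-recovery confusion check of
8 replicates per generating model at 20 subjects (diagonal dominance).
The published empirical quantities -- acceptance rates, chi-square values,
the BIC column 15,120/14,703/14,683/14,643, the margin of 40, the 99%
interval [1.07; 1.38] -- require the unreleased human data and are out of
scope; the procedures that would produce them are what the package tests.

## Limitations

Only a single random intercept per subject is supported -- no random
slopes, crossed effects, or non-logit links, matching the reference
analyses. Marginal means are evaluated at the random-effect mode zero
(subject-average log-odds), not integrated over the random-effect
distribution, so they are conditional rather than population-averaged
probabilities. The simulator's logistic choice rule makes
generative-model recovery a consistency check, not evidence about human
behaviour. And with all value models being monotone transforms of the
same six-level factor, model discrimination rests entirely on the shape
of the acceptance curve across those six points; designs with more
information levels would discriminate more sharply.
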