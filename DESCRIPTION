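Package: infolottery
Title: Information-Value Models of Non-Instrumental Information and Risky Choice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modelling how non-instrumental information -- advance
    previews of a lottery outcome that cannot change it -- alters the
    willingness to gamble. Implements four formula-defined "Information Value"
    models for a five-window slot-machine task (baseline, linear, Shannon
    entropy reduction over lottery permutations, and early resolution of
    uncertainty), a generative simulator of the task's three experimental
    designs, logistic mixed-model fitting with subject-specific random
    intercepts (Type II Wald chi-square tests, marginal means, Holm-adjusted
    pairwise contrasts), BIC-based model comparison with parametric bootstrap
    confidence intervals, and noncentral chi-square power analysis for
    Cohen's w effect sizes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    car,
    emmeans,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
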