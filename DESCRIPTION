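Package: expofactor
Title: Exposome Factor Modeling with Mixed-Type Correlations and Bifactor Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces wide panels of mixed-format environmental exposure
    variables (continuous, ordinal, binary) to a general exposome factor plus
    orthogonal domain subfactors. Estimates mixed-type correlation matrices
    (Pearson, polyserial, polychoric) with pairwise deletion and
    positive-semidefinite smoothing, performs minres exploratory factor
    analysis with oblimin and iterated target rotation, runs an auditable
    iterative redundancy-reduction loop, fits quasi-confirmatory bifactor
    models by unweighted least squares with fit indices (CFI, RMSEA, SRMR)
    and bifactor reliability indices (ECV, omega-hierarchical, factor
    determinacy), computes regression-method factor scores, and quantifies
    factor-outcome associations via standardized linear models, delta
    R-squared comparisons, logistic odds ratios, demographic contrasts and
    cluster random-intercept sensitivity models. A synthetic-cohort generator
    with planted bifactor structure, family clustering and planted outcome
    effects makes every stage testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
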