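Package: spscale
Title: Spatial Scale Selection for Area-Level Covariates in Regression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for choosing the geographic scale at which area-level
    covariates enter regression models of an individual-level outcome.
    Implements four constrained variable-selection path algorithms (forward
    stepwise, incremental forward stagewise, least angle regression, and the
    lasso) in which each conceptual covariate, observed at several nested
    census scales, may enter a model at exactly one scale. Includes OLS
    refits with AIC-based model choice, single-scale comparison models,
    nested random-intercept linear mixed models, clinician-specified
    interaction analyses, and a hierarchical synthetic cohort generator for
    nested census geographies.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    lme4,
    yaml
Suggests:
    glmnet,
    nlme,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
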