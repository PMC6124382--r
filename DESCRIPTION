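Package: samgsrl
Title: Pathway-Guided Feature Selection for Longitudinal Gene Expression
    via Two-Level SAMGSR
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the two-level significance analysis of microarray
    gene set reduction (SAMGSR) algorithm for selecting relevant
    (gene, time point) features from two-class longitudinal gene
    expression studies, together with the longitudinal-SAMGSR and
    per-time-point SAMGSR comparators.  Provides time-point-specific SAM
    statistics with a permutation-based gene-set test, the iterative
    core-subset reduction engine, classifier-based evaluation
    (misclassification error, generalized Brier score, belief confusion
    metric, area under the precision-recall curve) with posterior
    averaging across time points, 5-fold cross-validation tuning of the
    reduction cutoff, and a self-contained simulation benchmark with a
    synthetic longitudinal backbone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
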