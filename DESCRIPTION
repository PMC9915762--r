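Package: subspaceBind
Title: Semi-Orthogonal Value Subspaces, Binding and Generalization in
    Neural Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying how neural populations bind
    offer value to spatial position through semi-orthogonal population
    subspaces during risky choice. Provides a synthetic-data generator for
    the task (Prelec-warped power-utility softmax choices) and for neural
    populations following a linear-nonlinear code; per-neuron regression
    models with exact leave-one-out Bayesian model stacking and
    permutation ANOVA; population value-subspace correlations with
    bootstrap noise ceilings and a link to suboptimal-choice behavior;
    cross-validated (crossnobis) distance estimation with a
    linear-nonlinear geometric decomposition; closed-form binding and
    cross-condition generalization (CCGP) error-rate predictions validated
    against Monte-Carlo decoder oracles; pseudopopulation SVM decoding;
    and population-structure statistics including a Hartigan dip test of
    bimodality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    splines,
    jsonlite,
    e1071,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
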