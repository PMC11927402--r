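Package: cateselect
Title: Causal Model Selection for Conditional Average Treatment Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to select outcome (g-computation) models for estimating
    conditional average treatment effects (CATE). Implements the family of
    causal model-selection risks built on the Robinson decomposition -- the
    factual mean squared error (mu-risk), its inverse-propensity-weighted
    version, the pseudo-outcome tau-risk-IPW, the U-risk and the R-risk --
    in semi-oracle (true nuisance) and feasible (estimated nuisance) forms;
    a train/test selection procedure with stacked nuisance estimation
    (penalized linear plus gradient-boosted trees, hyperparameters set by
    nested cross-validation); a ground-truth simulator of potential-outcome
    data built on random radial-basis-function expansions with a
    controllable treated/control overlap parameter; and a benchmarking
    harness that scores each risk's candidate ranking against the oracle
    precision-in-estimating-heterogeneous-effects (PEHE) criterion with
    Kendall rank agreement and excess risk, stratified by overlap
    (normalized total variation) and effect-to-baseline ratio.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    xgboost,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
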