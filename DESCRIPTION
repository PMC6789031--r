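Package: soctouch
Title: Cortical Single-Unit Analysis of Naturalistic Social Facial Touch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for cortical single-unit recordings during
    naturalistic social facial touch. Models spike trains as Poisson
    point processes with spike-history, recording, touch and partner-sex
    terms; assesses touch and sex-touch modulation with circular-permutation
    and partner-label shuffle nulls; computes an information-per-spike
    statistic over stimulus categories; fits a bias-versus-potentiation
    mixed-effects model of population modulation; simulates a layered
    leaky integrate-and-fire cortical microcircuit with thalamic touch
    input and inhibitory-drive neuromodulation; and classifies units into
    putative excitatory/inhibitory classes from extracellular spike shape.
    Includes calibrated synthetic-session generators so every stage is
    testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
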