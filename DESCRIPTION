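Package: rosscreen
Title: In Silico Screening of Plant-Defense-Activator Candidates from
    Predicted Reactive Oxygen Species Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A virtual-screening toolkit for plant-defense-activator
    discovery. Learns to predict elicitor-triggered reactive oxygen
    species (ROS) production in plant cells from multidimensional
    chemical descriptors, screens large compound libraries against a
    log10-ROS modulator threshold, and performs a chemical-space
    secondary selection of candidates near known ROS modulators using
    generative topographic mapping (GTM). Includes a from-scratch SMOTE
    oversampler for the minority modulator class, random-forest
    descriptor-importance selection, a compiled multilayer-perceptron
    regressor with a random-forest baseline, screening-funnel
    accounting, and a synthetic compound-library generator with a
    planted structure-activity relationship for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ranger,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
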