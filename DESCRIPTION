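Package: twinmotion
Title: Twin Modelling of fMRI Head Motion and ADHD Symptom Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-subject head-motion summaries from fMRI rigid-body
    realignment parameters (Jenkinson RMS displacement over an 80 mm brain
    ball, gross-motion and outlier flags) and estimates heritabilities and
    genetic/environmental correlations between head motion and ADHD symptom
    scores with maximum-likelihood twin models. Provides a full-information
    maximum-likelihood (FIML) objective for pair-structured family data with
    missingness, saturated and ACE/ADE/AE variance-component models with
    Cholesky and variance-share parameterizations, sibling-contrast and
    sex-limitation extensions, likelihood-ratio homogeneity tests, profile
    likelihood confidence intervals, and a synthetic twin-cohort generator
    for end-to-end testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
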