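Package: hrnegsig
Title: Prognostic Gene-Signature Discovery for Hormone Receptor-Negative
    Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and evaluation of multigene prognostic signatures for
    node-negative, hormone receptor-negative and triple-negative breast
    cancer from multi-source gene-expression cohorts. Implements per-source
    preprocessing (centering, Z-transform, variance filtering, probe
    collapse, HER2 assignment from ERBB2 transcript levels), batch-aware
    cohort merging, a nearest-shrunken-centroid (PAM) cross-source screen,
    a Monte-Carlo cross-validation univariate Cox screen with
    sign-consistency filtering, hold-out confirmation, a sign-corrected
    unweighted composite expression index, Kaplan-Meier and Cox evaluation
    of dichotomized indices, cut-point optimization restricted to central
    percentiles, stepwise gene prioritization, multi-signature prognostic
    comparison, and a synthetic multi-source expression/survival cohort
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
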