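Package: cxrtriage
Title: Prioritisation of AI-Detected Chest X-Ray Findings for Cancer Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for configuring and evaluating chest X-ray AI triage from
    shadow-mode exports. Reads binary study-by-finding matrices for a confirmed
    lung-cancer cohort and a general referral cohort, ranks findings by their
    prevalence ratio between the cohorts, applies triage configurations
    (per-study OR rules over selected findings), and models specificity, PPV
    and NPV in the referral cohort under an assumed detectable-cancer
    prevalence via a pseudo confusion matrix. Includes prevalence and
    ratio-threshold sensitivity sweeps, exhaustive and greedy Pareto-frontier
    search over candidate finding sets, a correlated-binary cohort simulator
    (one-factor Gaussian copula), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'findings-io.R'
    'prevalence.R'
    'triage-metrics.R'
    'sweeps.R'
    'configurator.R'
    'synthetic.R'
    'cli.R'
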