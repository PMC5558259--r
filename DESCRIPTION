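Package: grstrial
Title: Genetic Risk Score Construction, Risk Updating and Randomized-Trial
    Analysis for Coronary Artery Disease
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Implements the computational chain of a pilot randomized trial
    that communicated a 19-SNP coronary-artery-disease genetic risk score
    (GRS): weighted score construction from genotype dosages and
    normalization against a reference cohort, genetic updating of Framingham
    10-year risk via a per-SD relative risk, eligibility screening and
    permuted-block randomization, carry-forward missing-data rules, and
    Hodges-Lehmann shift estimation with rank-sum inference for arm
    comparisons, including pre-specified high-GRS and medication-attitude
    subgroup analyses. A synthetic-data module generates Hardy-Weinberg
    reference cohorts with a configurable per-SD relative risk and two-arm
    three-visit trial datasets with dropout and item missingness, so the
    whole pipeline is testable without any participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
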