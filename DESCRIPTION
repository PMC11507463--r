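Package: kinfuse
Title: Kinship Inference Evaluation for Forensic Genetic Genealogy with
    IBD Segment Detection and Estimator Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for SNP-based kinship
    inference as used in forensic investigative genetic genealogy.
    Simulates pedigrees by gamete dropping on a genetic map with synthetic
    founder haplotypes, injects genotyping errors (drop-in, drop-out,
    switch), and estimates pairwise kinship with four approaches: a
    method-of-moments estimator from identity-by-state counts and three
    identity-by-descent segment detectors (IBS run-based, probability
    thresholded, and phased exact-match).  Relationship degrees (first to
    seventh plus unrelated) are classified from the kinship coefficient,
    performance is summarised as overlapping rate, sensitivity, positive
    predictive value and accuracy, and a stepwise linear fusion of the
    four estimators provides error-robust kinship prediction, including
    bundled published model coefficients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
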