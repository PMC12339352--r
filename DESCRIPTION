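Package: satol
Title: Saline-Alkali Tolerance Evaluation and Association Mapping for Rice Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comprehensive evaluation of saline-alkali (salt)
    tolerance in rice resource populations grown in multi-year two-treatment
    field trials, and for mapping the loci underlying it. Implements
    descriptive and Shannon-Weaver diversity statistics, per-group Pearson
    correlation matrices, correlation-matrix principal component analysis with
    component-retention rules, Ward hierarchical clustering, three-factor
    analysis of variance, REML variance components and multi-environment
    broad-sense heritability, the stress/control salt-tolerance index with
    fuzzy membership-function scoring into a comprehensive tolerance value D,
    and a mixed-linear-model genome-wide association scan (EMMA-style REML
    with P3D) of D with Bonferroni thresholding and candidate-region gene and
    variant annotation. A synthetic field-trial generator with known ground
    truth (variance components, causal markers, true tolerance ranking)
    supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    car,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
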