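Package: aggvar
Title: Severity-Weighted Aggregative Rare-Variant Association Tests
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conservation-aware scoring of coding variants and gene-level
    case-control association testing. Trains a conservation-controlled
    amino-acid substitution severity matrix from disease and neutral training
    variants, scores genes with a severity-weighted composite binomial
    likelihood-ratio test with rare-variant collapsing, permutation and
    asymptotic significance, and genome-wide ranking. Includes weighted-sum
    and carrier-burden baseline tests, simulators for population-attributable-
    risk case-control cohorts, stratified null cohorts and Mendelian spike-in
    benchmarks, and a ROC / power / false-positive-rate evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
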