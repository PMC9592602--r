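Package: pathdnf
Title: Pathway-Centric Drug Network Fusion and Permutation Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Integrates three drug-drug similarity layers -- Tanimoto
    similarity of extended-connectivity fingerprints, Pearson correlation of
    cell-line sensitivity profiles, and Pearson correlation of
    pathway-restricted drug perturbation signatures -- into a single fused
    drug network by similarity network fusion. Compounds are ranked against a
    reference drug and specificity to the pathway gene set is assessed with a
    random-gene-set permutation test (z-score and normal-approximation
    p-value). Includes a covariate-adjusted linear model for computing
    standardized drug perturbation signatures from expression experiments, a
    synthetic panel generator with planted drug communities for calibration
    and benchmarking, readers and writers for the delimited-matrix, GMT,
    fingerprint, edge-list and GraphML formats involved, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    xml2
Suggests:
    ChemmineOB,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
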