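Package: snpdist
Title: Genotype Hamming Distances, MDS Embedding and Case-Control Separation Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for measuring genetic distance between individuals from
    case-control SNP genotype data. Reads genotype matrices from VCF, PLINK 1
    binary and plain-text genotype tables; applies quality control (call rate,
    allele count, Hardy-Weinberg exact test) and classifies variants into
    common, low-frequency and rare classes by minor allele frequency; computes
    pairwise Hamming, normalized-Hamming and identity-by-state distance
    matrices over chosen variant sets; embeds distance matrices by classical
    (Torgerson) multidimensional scaling; and tests case-control mean
    separation in the MDS plane with a two-sample Hotelling's T-squared test.
    Includes a synthetic diploid cohort generator with class-specific
    allele-frequency divergence for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
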