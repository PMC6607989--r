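Package: varsieve
Title: Family-Based Prioritization of Low-Frequency Variants in Candidate Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for prioritizing low-frequency exonic variants in
    disease candidate genes from family and cohort sequencing data.
    Implements a pedigree-based filtering cascade (candidate-gene
    restriction, minor-allele-frequency threshold, read-fraction genotype
    calling, affected-carrier and parent-child transmission criteria),
    fixed-reference and pooled two-proportion z-tests of cohort allele
    frequencies against reference panels with Bonferroni correction, odds
    ratios with Woolf confidence intervals, per-patient carrier-combination
    tabulation, an exon-length-normalized permutation burden test over
    random gene sets, loss-of-function variant classification with a
    likelihood-ratio (G) test on 2x2 counts, and a synthetic-data module
    that generates pedigrees, cohorts, gene universes and reference panels
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    rtracklayer,
    vcfR,
    GenomicRanges,
    S4Vectors,
    stats,
    graphics,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
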