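Package: droughtsel
Title: Selection of Drought-Responsive Genes from Paired Tolerant/Sensitive
    Cultivar RNA-Seq Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-transcriptomics pipeline for identifying
    drought-responsive genes from pairs of drought-tolerant and
    drought-sensitive cultivars sampled over a drought time course.
    Provides count-matrix input/output with isoform-to-gene aggregation and
    library-size normalization, a negative-binomial Wald test for per-gene
    two-group comparisons, a three-round gene-selection cascade with a
    stable-reference-gene filter, cross-platform and cross-species
    expression-direction concordance tabulation, relative water content
    (RWC) physiology statistics with an exact Mann-Whitney U test, and a
    synthetic-data generator with ground-truth labels so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
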