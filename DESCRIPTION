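Package: gliotad
Title: TAD-Aware Analysis of Grade-Specific Gene Regulation in Glioma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical pipeline for studying grade-specific gene regulation
    in glioma through the lens of topologically associating domains (TADs).
    Provides rank-based differential calling of expression and promoter
    epigenetic marks between tumour grade groups, binomial TAD-enrichment
    tests for differential genes, Kruskal-Wallis fold-change homogeneity
    within TADs with a permutation null, bivalent-chromatin detection with a
    hypergeometric TAD-overlap test, enhancer calling from H3K27ac peaks with
    contact-map based gene-enhancer linking, grade-specific enhancer
    acetylation and methylation testing, transcription-factor target
    correlation filtering against randomized-target envelopes, and a
    synthetic-cohort generator that emulates the joint structure of
    multi-assay glioma data for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
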