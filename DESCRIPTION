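Package: isgland
Title: Interferon-Stimulated Gene Landscape Classification from Factorial
    RNA-seq and Chromatin Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Negative-binomial Wald differential expression for a genotype
    by interferon 2x2 factorial design with median-of-ratios normalization
    and Benjamini-Hochberg adjustment; four-contrast set logic that
    classifies genes into typical and atypical interferon-stimulated gene
    (ISG) classes and heatmap clusters, with subdivision of atypical ISGs
    into reported, hidden (ISRE/GAS motif-bearing) and non-canonical
    classes; position-weight-matrix promoter scanning for ISRE, IRE, GAS
    and NF-kB motifs with two-tailed hypergeometric motif enrichment of
    differential chromatin regions; TSS-distance annotation and
    differential calling for ATAC/H3K27ac peak sets; and a synthetic-data
    generator that plants known gene classes, motif instances and
    differential peaks so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
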