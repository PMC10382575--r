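Package: episplicer
Title: Associating Differential Exon Usage with Differential Histone Modification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for calling "epispliced" genes: genes whose
    per-exon differential usage between two cell types correlates with differential
    histone-modification signal (MA-normalized M-values) at 200-bp exon flanks.
    Provides flattening of transcript annotations into disjoint exon counting bins
    with gene-cluster exclusion filters, a simplified exact test for differential
    exon usage, MA-plot normalization and testing of ChIP-seq peak densities,
    flank annotation with per-region peak selection and FDR pooling, odds-ratio /
    Fisher co-occurrence analysis of DEU and DHM events, per-gene DEU-M correlation
    with epispliced calling, non-ubiquity and pooled significance filters, Jaccard
    similarity of epispliced gene sets with hierarchical clustering scored by the
    adjusted Rand index, hypergeometric term enrichment, and a seeded synthetic-data
    generator with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
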