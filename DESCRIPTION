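Package: crescan
Title: Conserved Regulatory Element Discovery and Deletion qPCR Analysis
    for Receptor Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers candidate cis-acting enhancers in olfactory receptor
    gene clusters by combining phylogenetic conservation, intergenic and
    non-repetitive filtering, degenerate (IUPAC) motif scanning with exact
    match probabilities, cross-species motif conservation calls, and
    shared-homology block detection with Benjamini-Hochberg false discovery
    control. Also quantifies the effect of enhancer deletions on cluster
    gene expression from qPCR cycle-threshold tables using the 2^-ddCt
    method with multi-gene housekeeping normalization, one-way ANOVA on
    dCt values, and Dunn-Sidak correction. Ships a synthetic-data module
    that emulates a ~200 kb receptor cluster, orthologous sequences across
    species, conservation tracks, and qPCR tables with recorded ground
    truth, so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
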