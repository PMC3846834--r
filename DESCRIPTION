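Package: mircnv
Title: Comparative Analysis of miRNA Regulation of Copy-Number-Variable
    Genes Across Species
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a cross-species atlas of homologous genes inside and
    outside copy number variation (CNV) regions, predicts microRNA binding
    sites in 3'UTRs with two independent algorithms (canonical seed-match
    site types and a longest 5'-complementarity scan) and intersects them
    at the miRNA-gene pair level, partitions genes by above/below-mean
    miRNA targeting, tests pathway and curated gene-class enrichment with
    Fisher's exact test and Benjamini-Hochberg correction, runs
    binding-site overrepresentation analysis, and scans miRNA genomic
    coordinates against gene spans to count host-gene-resident miRNAs.
    Includes a synthetic multi-species cohort generator with planted
    effects so the full pipeline is testable without external databases.
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
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
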