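Package: srnacore
Title: Small RNA-Seq Classification, Source Species Identification and
    Alignment-Free Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Core computational stages for small RNA sequencing analysis:
    harmonization of overlapping annotations from heterogeneous databases
    with RNA-type prioritisation, filtering of reads matching environmental
    (no-template) control libraries, two-pass ranking-based identification
    of the source species of reads from tabular BLAST-style hits with
    construction of a combined metagenome reference, priority-aware feature
    counting with coverage-guided placement of multi-mapping reads, and
    alignment-free differential expression of exact unique read sequences
    with greedy centroid clustering and consensus calling. Ships a
    deterministic fixture simulator (toy genomes, deliberately overlapping
    annotations, 10-44 nt reads, environmental controls, an exhaustive toy
    aligner) so the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    edgeR,
    data.table,
    stringi,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
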