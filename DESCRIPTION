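Package: ucetools
Title: Discovery, Tracing and Annotation of Ultraconserved Elements
    Across Multiple Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A k-mer based pipeline for discovering ultraconserved elements
    (UCEs) across sets of genome assemblies: canonical k-mer indexing, core
    k-mer selection across species, pigeonhole seed-and-verify approximate
    mapping, merging of core k-mer hits into candidate regions, and calling
    of maximal reference windows satisfying configurable length, identity
    and species-fraction thresholds, with cumulative multi-identity scans
    and repeat filtering by a multi-mapping cap. Also provides cross-species
    UCE tracing with a glocal aligner under Karlin-Altschul statistics,
    genomic-context classification against gene annotation, flanking-gene
    synteny assessment, a synthetic multi-genome simulator with implanted
    conserved elements, and an exhaustive brute-force UCE finder for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    methods,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
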