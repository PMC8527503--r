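Package: ctenotools
Title: Genome Analytics for Highly Heterozygous Chromosome-Scale Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis procedures for chromosome-scale genome assemblies of
    highly heterozygous animals: depth-conditioned heterozygosity estimation
    from read pileups, detection and census of nested intronic genes in GFF3
    annotations, reciprocal-best-hit microsynteny block chaining with Oxford
    dot-plot summaries, trans-spliced-leader motif scanning, and a
    size-preserving permutation test for the proximity of topologically
    associating domain (TAD) boundaries to genes.  Seeded synthetic-data
    generators produce pileups, annotations, ortholog tables, leader-bearing
    sequences and TAD landscapes with recorded ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
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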