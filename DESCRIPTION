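Package: cgrtools
Title: Reconstruction and Null-Model Analysis of Complex Genomic Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing copy-number-neutral complex genomic
    rearrangements (chromoanagenesis) on a single chromosome: assembly of the
    derivative-chromosome path from breakpoint junctions with classification of
    inversions as pericentric or paracentric, nucleotide-level junction
    signature calling (blunt fusion, microhomology, insertions with
    templated-origin search) with repair-mechanism inference (NHEJ/MMEJ versus
    replicative), and a Monte Carlo null model that contrasts breakpoint
    clustering (chromothripsis-like) with protein-coding-gene fusion
    enrichment (chromoplexy-like) via empirical p-values. Includes a fully
    synthetic data generator so every stage is testable without downloads, and
    readers/writers for junction TSV, BED, FASTA and VCF breakend records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
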