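Package: callingCards
Title: Transposon Calling-Card Insertion Mapping and Poisson Peak Calling
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of piggyBac transposon calling-card experiments that map
    the genomic binding of a protein fused to the transposase. Insertions are
    restricted to TTAA tetranucleotides, so enrichment is assessed per TTAA
    site: foreground hops are clustered into candidate peaks (maximum inter-hop
    gap 5 kb) and each peak is tested for Poisson enrichment against a
    background (unfused transposase) library, with the expected hops-per-TTAA
    rate estimated locally as the maximum over three nested windows around the
    peak. Includes nearest-gene and transcription-start-site annotation with
    Mann-Whitney distance comparisons against random genomic positions,
    integration of per-gene insertion burden with differential-expression
    responses (Fisher's exact association, responsive and strong target
    selection), and a deterministic synthetic-data generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    BiocGenerics,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
biocViews: FunctionalGenomics, PeakDetection, Transcription, Sequencing,
    GeneRegulation, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
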