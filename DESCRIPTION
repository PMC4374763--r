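Package: prophactr
Title: Prophage Identification and Particle-Protected DNA Activity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome- and sequencing-based analysis of prophage regions in
    bacterial chromosomes. Predicts candidate prophage loci from phage-protein
    homology clustering, evaluates region boundaries via GC content and
    flanking direct repeats (attL/attR), classifies prophage proteins by
    global Needleman-Wunsch best hits against a phage protein database, and
    quantifies prophage activity from particle-protected DNA read mappings
    using per-base coverage, NPKM normalization, signal-to-noise statistics
    and enrichment-based active-region calling. Includes a synthetic-data
    generator producing genomes with planted prophages and particle-derived
    read sets with truth alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
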