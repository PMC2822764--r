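Package: TandemArrays
Title: Genome-Wide Prediction of Tandem Gene Arrays and Gene Relics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects tandem gene arrays (TGAs) in compact genomes by
    translated similarity search in the chromosomal vicinity of each
    annotated coding sequence. Each CDS protein is aligned against both
    strands of its upstream and downstream flanking windows
    (Waterman-Eggert multi-HSP local alignment with BLOSUM62 and
    Karlin-Altschul bit scores), bit scores of compatible HSPs are summed
    into TB scores, normalised by a TB self-score and strand-differenced
    into FTB scores, from which a position automaton assembles arrays,
    allowing one spacer gene and tagging candidate gene relics in
    intergenic DNA. Includes dotplot-based relic confirmation,
    minisatellite (tandem repeat) screening of array members, a synthetic
    genome generator with planted truth for validation, summary reports
    and a parameter-sweep harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
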