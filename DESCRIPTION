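Package: polyAscreen
Title: Poly(A)-Site Calling and Template-Switching Artifact Filtering
    for Long-Read cDNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls candidate polyadenylation (poly(A)) sites from long-read
    cDNA alignments and screens them for reverse-transcription artifacts.
    Template-switching artifacts are separated from genuine transcript end
    sites with a counter-based adenine score of the upstream window and a
    logistic read-proportion threshold; classical internal-priming,
    SQANTI-style and PolyA_DB-style filters are provided as baselines.
    Includes direct-RNA-based confirmation with positive/negative
    predictive value evaluation, polyadenylation-signal motif detection,
    Smith-Waterman poly(A)-tail length measurement, and a seeded simulator
    of cDNA/dRNA alignments with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
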