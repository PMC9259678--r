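Package: metamerge
Title: Consolidation of De Novo Transcriptome Meta-Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Merges the outputs of multiple de novo transcriptome assemblers
    into a non-redundant reference. Implements expression-based transcript
    filtering (per-condition TPM and mean-abundance thresholds), greedy
    incremental identity clustering of near-duplicate transfrags, simplified
    coding-sequence consolidation of transcripts into gene groups,
    containment-based redundancy removal, assembly quality statistics
    (N50, GC content, length distributions), and a screening rule for
    microRNA precursor candidates that combines hairpin classifier scores
    with mature-miRNA matching. A seeded synthetic-transcriptome generator
    with a ground-truth manifest supports end-to-end validation, and a
    pipeline driver chains the stages with a per-stage report ledger.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
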