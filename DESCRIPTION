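Package: hicforge
Title: Hi-C Data Processing, Normalization, and TAD Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for paired-end Hi-C data: in-silico
    restriction digestion and fragment-end (FEND) annotation (length, GC
    content, k-mer mappability), ligation-junction read pre-truncation,
    MAPQ/duplicate/artifact read-pair filtering, explicit-factor contact
    matrix normalization with distance-decay estimation, observed/expected
    analysis, directionality-index TAD calling via a three-state Gaussian
    hidden Markov model, heatmap and DI visualization, and a run-length
    compressed text storage format for symmetric sparse contact matrices.
    Includes a deterministic synthetic-data generator with recorded ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    data.table,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
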