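Package: editscan
Title: Detection, Curation and Annotation of Plastid RNA Editing Sites
    from RNA-seq Read Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies C-to-U and U-to-C RNA editing sites in plastid
    transcriptomes by comparing aligned RNA-seq reads against the plastid
    genome sequence. Builds per-position pileups under several read-end
    trim treatments, types every DNA:RNA mismatch, and calls candidate
    sites with a joint read-depth and mismatch-frequency rule. Four
    classes of false-positive signal (heteroplasmy among plastid genome
    copies, random-hexamer mispriming errors at read ends, mismapping of
    spliced reads across exon/intron junctions, and reference-genome
    errors) are detected with explicit, configurable rules, and
    reference errors trigger genome correction and a second calling
    pass. Curated sites are annotated with location class, codon-level
    consequences, per-site editing efficiency, and a
    conservative/silent/non-conservative functional classification
    against cross-species protein alignments; homologous sites are
    compared across species through those alignments. A seeded
    simulator produces a miniature plastid-like genome, annotation,
    edited RNA and DNA read sets with all four artifact classes
    injected, and a ground-truth table, so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    data.table,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
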