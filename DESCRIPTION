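Package: capFL
Title: Full-Length Read Evaluation for Cap-Selected Long-Read cDNA Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate how well a long-read cDNA library captures
    genuine full-length transcripts. Reads spliced long-read alignments (PAF)
    against a GFF3 annotation, classifies each read as full length when it is
    at least as long as its spliced target, profiles signed 5'/3' alignment-end
    offsets around annotated transcription start and end sites, compares two
    library chemistries (cap-dependent linker ligation versus template
    switching) with exact or tie-corrected Mann-Whitney tests per size
    fraction, estimates residual read redundancy by end-tolerant single-linkage
    clustering, resolves reads mapping to multiple homeologous loci by a
    best-alignment-match criterion, and classifies reads against the annotation
    by intron chain (known isoform, novel isoform, novel locus). Includes a
    seeded simulator of the two chemistries over a synthetic multi-exon
    annotation, with per-read ground truth, used for validation throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
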