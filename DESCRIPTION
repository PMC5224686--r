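Package: trftools
Title: tRNA-Derived Fragment Discovery, Seed Prediction and Target
    Regulation Analysis in Aging Brain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end small-RNA analysis pipeline for tRNA-derived
    fragments (tRFs). Maps adapter-clipped small-RNA reads exactly onto
    mature tRNA sequences (including the post-transcriptional CCA tail),
    classifies fragments as 5', 3'CCA or internal, applies
    reads-per-million normalization and a per-replicate abundance filter,
    and labels age trajectories across a three-timepoint design. Candidate
    seed regions are identified by sliding 7-mer windows along each tRF
    and counting conserved 7mer-m8/7mer-1a/8mer-1a target sites in
    multi-species 3'UTR alignments against two null models (genomic 7-mer
    frequency and a same-composition permutation null). Age-related
    down-regulation of predicted target sets is quantified with a
    resampling statistic. A synthetic-data module generates all inputs
    with planted ground truth so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
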