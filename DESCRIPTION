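Package: cuticleCourse
Title: Time-Course Analysis of Pupal Wing Cuticle Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of a seven-time-point (42-96 hr after white
    prepupa) bulk RNA-seq time course of Drosophila pupal wing cuticle
    deposition. Provides stage-specificity scoring of FPKM trajectories,
    Jensen-Shannon distance and deterministic partitioning-around-medoids
    (PAM) clustering with silhouettes, fold-change screens for candidate
    transcription factors, dominant-isoform switch detection, amino-acid
    composition screening of candidate cuticle proteins, cluster label
    enrichment statistics, delta-delta-Ct relative quantification of qPCR
    plates, cuticle-thickness ratio statistics, and seeded synthetic-data
    generators so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
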