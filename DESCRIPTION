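Package: dmrscape
Title: Downstream Analysis of Differentially Methylated Regions in Matched
    Tumor/Normal Methylomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the downstream analysis of 500-bp differentially
    methylated regions (DMRs) called between matched normal and tumor
    methylomes, as produced by MeDIP-seq/MRE-seq integrative callers.
    Provides comparison enumeration over a cohort manifest, Q-value
    threshold calibration, a position-stable unique-DMR catalogue with
    per-direction recurrence, log-odds-ratio enrichment over genomic
    features, repeat subfamilies and ChromHMM chromatin states,
    Jukes-Cantor repeat divergence summaries, clinicopathologic-category
    exclusive DMR detection with exhaustive label-permutation nulls,
    multi-resolution DMR density and hotspot detection, global methylome
    profiling, and a fully self-contained synthetic cohort generator with
    planted ground truth for end-to-end validation.
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
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
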