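Package: histodiff
Title: Differential H3K4me3 ChIP-Seq Analysis Between a Tumour and Its
    Matched Surrounding Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for paired-sample differential analysis of H3K4me3
    ChIP-seq: strand-shifted normalized coverage pileup, anchor-centered
    meta-profiles (TSS, TTS, CpG-island centers), per-gene peak gain/loss
    classification over promoter/exon/gene-body categories, detection of
    copy-number-amplified regions by read-count criteria with an
    upper-tail Poisson significance test, linkage of promoter signal to
    expression, and a fully specified synthetic-data generator with known
    ground truth for every stage. A single-process pipeline orchestrator
    with a deterministic manifest ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
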