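Package: methylsift
Title: Paired Tumor/Normal Methylome Candidate Discovery with In Silico
    CoBRA and Guide Placement Utilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Candidate-gene discovery from paired tumor/normal DNA
    methylation array data, built around the workflow that identifies
    isoform-specific CpG-island hypermethylation in renal cell carcinoma.
    Provides probe-level paired differential methylation testing with
    false discovery rate control, probe-to-gene candidate prioritization,
    per-CGI methylation aggregation and a two-isoform (A-hypomethylated /
    B-hypermethylated) signature classifier, in silico combined bisulfite
    restriction analysis (CoBRA) with bisulfite conversion, virtual PCR
    and methylation-dependent digest prediction, and promoter utilities
    for TSS-relative coordinates, E-box motif scanning and mismatch-based
    sgRNA off-target counting. A beta-distributed synthetic cohort
    generator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
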