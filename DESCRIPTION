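Package: bltseq
Title: Cleavage Quantification for Barcoded Libraries of CRISPR Targets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis of barcoded-library-of-targets (BLT)
    sequencing experiments that measure the absolute cleavage efficiency of
    a Cas9 ribonucleoprotein across large libraries of mismatched targets.
    Generates synthetic degenerate target libraries with unique molecular
    identifiers and writes realistic FASTQ reads; parses, demultiplexes,
    quality-filters and UMI-collapses reads into per-target cut/uncut
    observation counts; computes on-target-normalized cleavage efficiencies
    and guide-intrinsic mismatch permissiveness (GIMP) scores; estimates the
    probability of cleavage given Cas9 binding from bead pull-down
    experiments; trains guide-specific neural-network regressions on binary
    mismatch encodings; and enumerates, scores and ranks candidate genomic
    off-target sites within a mismatch budget.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    nnet,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
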