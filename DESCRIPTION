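Package: desertscan
Title: Windowed SNP Density Scans, Polymorphism Deserts and Selective
    Sweeps in Multi-Accession Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide SNP diversity analysis across several
    resequenced accessions mapped to a common reference: non-overlapping
    (tumbling) window SNP-density scans, detection and testing of
    "polymorphism deserts" (extended regions of drastically reduced SNP
    density), delineation of selective sweeps around candidate
    domestication loci at 1-kb resolution, coverage-filtered gene-level
    diversity with synonymous/nonsynonymous SNP classification, and an
    inhomogeneous-Poisson SNP landscape simulator with planted
    low-diversity regions and ground-truth output so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    zoo,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    ggplot2,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
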