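Package: parecall
Title: Degradome Sequencing Analysis of mRNA Stability, Endonucleolytic
    Cleavage and Decapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of 5'-monophosphate degradome tag libraries (PARE-seq)
    and capped-end tag libraries (C-PARE-seq) against a transcript annotation.
    Converts raw 20-nt tag reads into normalized per-transcript decay
    profiles; classifies transcripts as stable or unstable by comparing
    RNA-seq (FPKM) and degradome (DPKM) abundance with an exact
    negative-binomial count test and Benjamini-Hochberg false discovery
    control; calls endonucleolytically cleaved transcripts with a four-filter
    Max-seq cascade; infers empirical cap positions from C-PARE tags in
    +/- 200-nt transcription-start-site windows and calls decapped
    transcripts where degradome and capped-end maxima coincide. Includes a
    seeded synthetic-data generator with planted ground truth so every stage
    can be benchmarked without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
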