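Package: promepi
Title: CArG-Box Scanning, Phylogenetic Footprinting and Epigenetic Assay
    Quantification for MADS-Box Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for dissecting the regulatory regions of
    B-class MADS-box genes. Scans promoter sequences for CArG boxes under
    degenerate consensus rules with a mismatch budget, discovers short
    motifs conserved across paralogous promoters by substring parsimony on
    a phylogeny with allowed motif losses, calls per-cytosine methylation
    from bisulfite-treated clone sequences and predicts
    methylation-sensitive restriction digests (HpaII/MspI/DraI), and
    quantifies ChIP-qPCR enrichment (delta-Ct against an internal control)
    and dual-luciferase reporter activity with compact-letter-display
    significance groups. A seeded synthetic-data generator produces
    promoter sets evolved along a tree with planted motifs, bisulfite
    clone sets, and qPCR/luminometer tables with known ground truth, so
    the whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
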