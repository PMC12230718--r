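Package: irescan
Title: Prediction and Scoring of Iron-Responsive Elements in mRNA
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects iron-responsive elements (IREs), the RNA stem-loop
    motifs bound by iron regulatory proteins (IRP1/IRP2), in RNA or DNA
    sequences. Scans for degenerate apical-loop motifs from a curated
    registry, assembles full hairpin candidates (5-bp upper stem, unpaired
    N8 bulge, N7-N25 closing pair, optional single 3' bulged nucleotide),
    scores them on a penalty scale up to 8 with six confidence categories,
    checks concordance with minimum-free-energy secondary structure, and
    annotates predictions with their transcript location (5'UTR, 5'UTR-CDS,
    CDS, CDS-3'UTR, 3'UTR) and distances to the cap, start and stop codons.
    Includes benchmarking utilities (sensitivity, specificity, precision,
    balanced accuracy per pooled confidence tier) and a deterministic
    synthetic-fixture generator that plants IRE cores of every motif class
    in random backgrounds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
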