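Package: pnpscreen
Title: Neuropeptide Precursor Discovery and Settlement-Candidate Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: De-novo annotation of prohormone (neuropeptide precursor)
    proteins from transcriptome-derived sequences: signal-peptide and
    mono-/dibasic cleavage-site calling, mature-peptide extraction with
    C-terminal amidation and pyroglutamate flags, repeated-peptide motif
    discovery, and a candidate-precursor decision rule. Combines the
    de-novo calls with Smith-Waterman homology screening against a curated
    query panel (Karlin-Altschul E-values), assigns precursors to
    neuropeptide families and phylogenetic-distribution tiers from a
    reference catalog, screens stage-wise FPKM matrices for up-then-down
    larval-settlement expression patterns, and computes 2^-ddCt relative
    expression with ANOVA/Tukey compact letter displays for qPCR
    validation. Ships a seed-deterministic synthetic-data generator that
    plants multi-copy prohormones among decoy proteins, with machine
    readable ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
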