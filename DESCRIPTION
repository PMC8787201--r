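Package: xenoscan
Title: Full-Length Hybridization Scanning for Cross-Species miRNA Binding Sites
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts binding sites of exogenous (e.g. milk-borne bovine)
    miRNAs on mRNAs by scoring every window of a transcript against the full
    length of the miRNA with an additive per-pair hybridization free-energy
    model that includes the non-canonical G-U and A-C pairs. Sites are kept
    when the complementarity ratio (100 * dG/dGm) reaches a threshold,
    localized to the 5'UTR, CDS or 3'UTR, and grouped into clusters of
    tandem, overlapping sites with span, spacing and compaction metrics.
    Includes detection of GCC trinucleotide repeat runs and the homopolymer
    peptides (polyA, polyP, polyR) they encode in coding sequence, a seeded
    synthetic-data generator with planted ground truth for validation, and
    packaged fixtures for the published table-level counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
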