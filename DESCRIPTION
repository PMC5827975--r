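Package: sdpbench
Title: Temporal Benchmarking of Functional-Residue and Subfamily Detection in Protein Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs date-stamped historical versions of a protein family's
    multiple sequence alignment (publication-date filtering, 95 percent identity
    redundancy removal, minimum-size gating) and applies five sequence-based
    detectors of functional residues and subfamilies: fully conserved positions,
    an Xdet-like matrix-correlation method, an Evolutionary-Trace-like tree-cut
    rank, a TEA-O-like two-entropies score, and an S3det-like correspondence
    analysis with subfamily clustering. Performance is quantified as the relative
    distance of predicted residues to binding sites on a representative
    structure, and aggregated into per-year series relative to a reference year.
    A synthetic-family generator with planted subfamily structure, site classes,
    publication dates and a synthetic binding pocket makes the whole pipeline
    testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    bio3d,
    cluster,
    mclust,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
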