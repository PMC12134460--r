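Package: repairome
Title: Comparative Analysis of DNA Damage Response Protein Repertoires and
    Lengths Across Eukaryotes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing the DNA damage response (DDR) protein
    repertoire and protein length architecture across eukaryote proteomes.
    Builds human-anchored orthologue presence/length matrices from
    orthogroup tables, recovers orthologues missed by global clustering via
    a clade-reference bait rescue step, scores pathway preservation by
    species and lifestyle, decomposes proteins into functional-domain and
    interdomain lengths from Pfam hits (footprint and domain-density
    analysis), and runs the associated statistical comparisons (Spearman
    correlations, one- and two-way fixed-effects ANOVA, group length
    ratios). A seeded synthetic-world generator with known ground truth
    makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
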