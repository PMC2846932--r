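Package: lectinfam
Title: Gene-Family Evolution and Expression Divergence of Plant Lectins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide analysis of plant lectin gene-family
    evolution. Classifies genes into twelve carbohydrate-binding-domain
    families from profile-HMM hit tables, detects tandem clusters and
    segmental duplication blocks, identifies retrogene candidates by
    intron loss plus flanking target-site duplications and poly(A)
    tracts, classifies transposable-element overlap, counts ancestral
    gene lineages on species-labelled gene trees by LCA reconciliation,
    estimates per-ancestral-gene birth rates, and quantifies stress and
    tissue expression divergence of duplicated genes. Includes a seeded
    synthetic-genome generator with full ground truth so every stage of
    the pipeline is testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
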