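Package: minibarcode
Title: Barcode-Gap Analysis and Species Identification for ITS/ITS2
    Minibarcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate short DNA barcode loci ("minibarcodes") such
    as the nuclear ribosomal ITS2 against their full-length parent region.
    Provides a seeded synthetic-corpus generator with a genus/species/sample
    hierarchy and composite ITS architecture, profile-HMM excision of ITS2
    from full-length ITS via conserved 5.8S and 28S-flank motifs, exact
    pairwise global/local alignment with Kimura 2-parameter and uncorrected
    p-distances, the six standard inter/intraspecific divergence parameters
    with paired Wilcoxon signed-rank locus comparison, and three
    leave-one-out species-identification criteria (best hit, best match,
    best close match with a distance threshold), orchestrated by a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
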