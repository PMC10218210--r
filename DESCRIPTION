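Package: amyloscan
Title: Detection of Conserved Amyloidogenic Regions in Protein Ortholog Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating evolutionarily conserved amyloidogenic
    regions in families of orthologous proteins, motivated by the analysis of
    FG-repeat nucleoporins. Provides per-residue amyloidogenicity and
    intrinsic-disorder scoring (built-in surrogate scorers or imported
    predictor output), an amyloid-call rule combining both scores,
    taxon-balanced subsampling of ortholog groups, a progressive multiple
    sequence aligner with an affine-gap compiled core, projection of
    per-residue calls onto alignment columns, per-column gap fraction, amino
    acid conservation (AAC) and conservation of amyloidogenic properties
    (CAP) statistics with conserved-region calling, a per-taxon amyloid
    census, Fisher's exact comparison of aggregation assay counts, and a
    sequence-family simulator with planted motifs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
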