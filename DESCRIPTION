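Package: matesys
Title: Mating-System Analysis of Free-Ranging Dog Genealogies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising the genetic mating system of
    free-ranging domestic dog populations from reconstructed genealogies
    and SNP genotypes. Provides exact pedigree kinship (tabular method)
    and relationship-type classification up to the fourth degree, forward
    pedigree simulation under random-mating null scenarios with litter
    structure and capped female fecundity, Mendelian gene dropping for
    validating genotype-based relatedness estimators (method-of-moments
    IBD/PI-HAT and KING-robust kinship), genealogy-derived mating-system
    statistics (sibling structure, multiple paternity, repeated parental
    pairs, close inbreeding, Crow's opportunity for selection, Morisita
    reproductive skew), weighted proximity social networks with community
    detection, and observed-versus-null comparison via simulation
    ensembles and permutation envelopes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
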