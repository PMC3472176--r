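Package: gvpart
Title: Partitioning Additive Genetic Variance into Genomic and Polygenic
    Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for partitioning the additive genetic variance of complex
    traits into a component captured by genome-wide SNP markers and a residual
    polygenic component captured by pedigree relationships.  Builds pedigree
    (numerator) relationship matrices by the tabular method and VanRaden-type
    genomic relationship matrices (whole-genome and chromosome-split), fits
    mixed models with one or more correlated random effects and weighted
    heterogeneous residual variance by average-information REML, scans
    chromosomes for their contribution to genomic variance, and estimates the
    proportion of additive variance a marker panel of a given density can
    explain via split-panel regression of genomic relationships.  Includes a
    gene-dropping simulator of sire-heavy dairy-cattle-like populations
    (pedigree, genotypes, QTL, deregressed-proof-like phenotypes) so that
    every stage can be validated against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
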