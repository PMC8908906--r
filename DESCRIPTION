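Package: hetdom
Title: Genomic Heterozygosity, Heterosis and Dominance Association Analysis for Crossbred Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the relationship between pedigree-based
    heterosis and genome-based heterozygosity in crossbred livestock, and for
    locating non-additive (dominance) SNP associations with quantitative
    traits. Implements pedigree heterosis and recombination-loss coefficients,
    three genomic heterozygosity measures (observed heterozygosity,
    homozygosity by locus and runs of heterozygosity via a sliding-window
    detector), the pedigree numerator relationship matrix with phantom-parent
    genetic groups, the VanRaden Method I genomic relationship matrix, a
    single-random-effect REML mixed model for heterozygosity-trait
    association, a two-stage additive plus dominance genome-wide scan with
    genomic-control diagnostics and Storey q-value FDR, and LD-based
    collapsing of significant SNPs into QTL regions. A gamete-dropping
    simulator generates crossbred cohorts with known trait architecture for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
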