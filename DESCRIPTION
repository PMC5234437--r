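Package: otuflow
Title: Downstream Analysis of 16S rRNA Amplicon OTU Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of microbial amplicon sequencing data
    starting from an OTU count table, a sample mapping file and a
    phylogenetic tree. Implements minimum-depth proportion normalization and
    optional rarefaction, alpha-diversity with effective (Hill) numbers,
    generalized UniFrac beta-diversity with PCoA/NMDS ordination, PERMANOVA
    and Ward clustering, taxonomic binning at every rank with propagation of
    unknown placements, prevalence- and median-gated nonparametric serial
    group comparisons with Benjamini-Hochberg correction, centred log-ratio
    based correlation analysis between meta-variables and taxa, and a
    Dirichlet-multinomial simulator for fully reproducible synthetic test
    data including technical-replicate libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    vegan,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
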