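Package: pondassembly
Title: Community Structure and Assembly-Process Partitioning for
    Amplicon Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ZOTU (zero-radius OTU) count tables from
    size-fractionated microbial eukaryote communities sampled across
    contrasting habitats such as Arctic melt ponds and surface sea water.
    Provides count-table input/output, min-count filtering and rarefaction,
    alpha diversity (richness, Shannon, bias-corrected Chao1, Faith
    phylogenetic diversity), Bray-Curtis and unweighted UniFrac
    dissimilarities with nMDS and PCoA ordination, permutation tests (ANOSIM,
    Mantel), SIMPER decomposition, and a phylogenetic null-model partition of
    community assembly processes: weighted beta mean nearest taxon distance
    (betaMNTD), the beta nearest taxon index (betaNTI), the Bray-Curtis based
    Raup-Crick metric (RC-bray), and the resulting five-way classification
    into heterogeneous selection, homogeneous selection, dispersal
    limitation, homogenizing dispersal, and drift. A synthetic metacommunity
    generator with known assembly regimes makes every stage testable without
    external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    vegan,
    picante,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
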