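Package: morelbiome
Title: Core-Bacteriome Delineation and Comparative Genomics for Fungal-Associated Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the bacterial communities associated with
    fungal structures (mycelium, sclerotia, fruiting bodies) from amplicon
    sequence variant (ASV) count tables: negative-control contaminant removal,
    non-bacterial filtering, total-sum scaling, genus agglomeration, layered
    core-community delineation over a prevalence-by-detection threshold grid,
    Bray-Curtis ordination by nonmetric multidimensional scaling with
    permutation-based group validation (PERMANOVA), and a comparative-genomics
    stage that clusters genes from pairwise protein bitscores (minbit filtering
    followed by Markov clustering), partitions gene clusters into core, unique
    and group-specific bins, and scores KEGG-module completeness. A synthetic
    community and pangenome simulator with known planted structure makes every
    stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
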