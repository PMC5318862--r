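Package: phyloflora
Title: Phylogenetic Structure and Beta Diversity of Regional Floras
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for phylofloristic analysis of regional checklists on a
    time-calibrated backbone phylogeny. Grafts listed taxa onto a backbone
    megatree (as polytomies, at random positions, or with BLADJ-style
    re-dating), derives family-, genus- and species-level analysis trees,
    and quantifies within-flora phylogenetic structure (NRI/NTI from
    MPD/MNTD) and between-flora phylogenetic beta diversity (PhyloSor and
    nearest-neighbour distance with standardized effect sizes) under
    tip-shuffle null models, optionally partitioned by geographical
    distribution elements. Includes a seedable synthetic-data generator
    (trees, taxonomies, communities with controlled clustering or
    overdispersion) so the whole pipeline is testable without external
    floristic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    phangorn,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
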