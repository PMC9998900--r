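Package: multidiv
Title: Multifaceted Taxonomic, Phylogenetic and Functional Diversity of
    Riparian Plant Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alpha and beta diversity analysis of plant communities along
    dam-regulated inundation gradients in three dimensions (taxonomic,
    phylogenetic, functional): Rao quadratic entropy on Gower trait
    distances, Faith's PD, MPD/MNTD with richness-preserving null-model
    standardized effect sizes, Sorensen-family decomposition of beta
    diversity into turnover and nestedness (species, shared-branch and
    functional variants), PCNM spatial eigenvectors, Mantel and partial
    Mantel permutation tests, and four-set variance partitioning with
    adjusted R-squared and forward selection.  Includes a synthetic
    community generator with known assembly processes (environmental
    filtering, dispersal limitation, nested loss, turnover, neutral) for
    ground-truth validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    stats,
    utils,
    yaml
Suggests:
    cluster,
    jsonlite,
    optparse,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
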