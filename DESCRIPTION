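Package: bifidoprof
Title: Species-Level Profiling of Gut Bifidobacteria from groEL Amplicons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to profile the human gut Bifidobacterium community from
    groEL marker-gene amplicon data and to relate its composition to host
    and environmental covariates. Builds a primer-trimmed groEL amplicon
    reference database from genome sequences, assigns taxonomy to denoised
    amplicon variants (ZOTUs) by reconciling hits against a general
    nucleotide database and the groEL database with a bit-score arbitration
    rule, converts ZOTU counts into composite species-level relative
    abundances on the whole-community scale, computes alpha and beta
    diversity including age trajectories, and provides an association
    battery for population studies of the bifidobacterial community:
    distance-based redundancy analysis with adjusted R-squared and forward
    selection, ridge-regression covariate screens, Mantel tests,
    ANOVA with Fisher's LSD letters, Mann-Whitney differential counts, and
    Benjamini-Hochberg correction. A synthetic cohort generator with
    planted covariate effects makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    geosphere,
    picante,
    stats,
    tools,
    utils,
    vegan
Suggests:
    MASS,
    jsonlite,
    phyloseq,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
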