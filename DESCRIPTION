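Package: equimicrobiome
Title: Gut Microbiota Dynamics and Microbiability in Horse Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for longitudinal gut-microbiota cohort
    studies: core-microbiota detection, alpha- and beta-diversity dynamics,
    permutation-based community inference (PERMANOVA, ANOSIM, SIMPER, NMDS,
    covariate fitting), PAM enterotyping with silhouette selection, and
    Bayesian estimation of microbiability (the fraction of host phenotypic
    variance attributable to the gut microbial community) from a microbial
    relationship matrix built on CSS-normalized log abundances. Includes a
    synthetic-cohort generator with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    cluster,
    ape,
    phyloseq
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
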