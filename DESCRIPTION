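Package: phyloAssembly
Title: Phylogenetic Null Models for Microbial Community Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers the ecological processes structuring microbial
    communities from phylogenetic and compositional turnover. Implements
    the standardized effect size of mean nearest taxon distance (SES.MNTD),
    phylogenetic beta-diversity (betaMNTD) and the beta-nearest taxon index
    (betaNTI) under the taxa-labels randomization, the abundance-based
    Raup-Crick metric (RC-bray) under a two-stage probabilistic assembly
    null, and the five-way partitioning of pairwise turnover into
    homogeneous selection, variable selection, homogenizing dispersal,
    dispersal limitation and undominated processes. Includes readers for
    Newick trees and OTU tables, rarefaction, a seeded synthetic-data
    generator (Yule trees, Brownian traits, communities assembled under
    known processes) and an end-to-end pipeline with provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    methods,
    phytools,
    stats,
    utils,
    vegan
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'communitySet.R'
    'io.R'
    'rarefy.R'
    'cophenetic.R'
    'nullmodels.R'
    'raupcrick.R'
    'partition.R'
    'simulate.R'
    'pipeline.R'
    'phyloAssembly-package.R'
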