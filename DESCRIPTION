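Package: cancerTBN
Title: Threshold Boolean Network Modeling of Integrated Cancer Signaling Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulator for threshold Boolean networks of cell signaling, built
    around a curated pan-pathway cancer network (PI3K/AKT, MAPK, WNT, TGF-beta,
    HIF-1, NF-kB, p53, apoptosis and cell-cycle modules). Provides synchronous
    threshold dynamics with exact integer arithmetic, attractor detection and
    exhaustive or Monte Carlo basin-of-attraction analysis, phenotype
    classification of attractors (apoptotic, proliferative, quiescent plus
    glycolytic, immortalized, migratory and mutator traits), in-silico mutation
    and targeted-therapy screens including a sequential colorectal
    carcinogenesis protocol, and network-topology characterization against
    random-graph null ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'AllClasses.R'
    'AllGenerics.R'
    'network-core.R'
    'builtin-network.R'
    'random-network.R'
    'dynamics.R'
    'phenotypes.R'
    'perturbations.R'
    'screens.R'
    'topology.R'
    'io.R'
    'cli.R'
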