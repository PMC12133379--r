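Package: pawebs
Title: Protection Effects on Avian Food-Web Structure
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the effect of protected areas on the structure
    of local avian food webs. Local webs are induced from a trophic metaweb by
    species co-occurrence on a 10 x 10 km grid; sixteen structural and
    body-size metrics are computed per grid cell; per-protected-area-network
    protection effects are estimated with generalized additive mixed models
    (variable-slope random effects plus penalized smooths for survey effort
    and richness); and the variation of those effects across networks is
    regressed on environmental drivers with BIC-stepwise selection. A
    synthetic-data generator reproduces the statistical structure of
    citizen-science occurrence data (uneven survey effort, biased reserve
    placement, network-heterogeneous protection effects) so the full pipeline
    is testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    mgcv,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Network, GraphAndNetwork, Regression, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'drivers.R'
    'effects_model.R'
    'foodwebs.R'
    'occurrences.R'
    'protected_areas.R'
    'synthetic.R'
    'pipeline.R'
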