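Package: ChinaCarbon
Title: Process-Based Carbon Balance Simulation for China's Terrestrial
    Ecosystems, 1900-2000
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A simplified process-based terrestrial ecosystem carbon-balance
    pipeline for China over the 20th century. Generates seeded synthetic
    gridded forcing (monthly climate, annual CO2, dynamic land cover, soil
    texture) with the statistical structure of the historical drivers,
    simulates monthly GPP, autotrophic and heterotrophic respiration, NPP
    and NEP per land-cover cohort together with soil temperature and a
    bucket water balance, runs the equilibrium / spin-up / transient
    protocol and the four-member factorial experiment separating CO2,
    climate and land-use effects, and provides the regional diagnostics:
    area-weighted national and biome totals, decadal means, linear trends,
    latitude/longitude strip anomalies, the Hu Huanyong line partition,
    carbon-source year counts, and Spearman and partial rank correlations
    of fluxes with their drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'ChinaCarbon-package.R'
    'grid.R'
    'forcing.R'
    'landuse.R'
    'soil.R'
    'carbon.R'
    'engine.R'
    'protocol.R'
    'aggregate.R'
    'io.R'
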