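Package: woodfall
Title: Biogeochemistry and Bacterial Community Analysis of Deep-Sea Wood Falls
Version: 0.1.0
Authors@R:
    person("Benthic", "Biogeochemistry Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the biogeochemical and microbial footprint of
    sunken wood on the deep seafloor: diffusive fluxes from microsensor
    concentration profiles via Fick's first law (including sulfide speciation
    from paired H2S/pH profiles), total oxygen uptake from benthic chamber
    time series, whole-core radiotracer turnover rates with depth integration,
    a wood-carbon persistence budget, fixed-window binning of ARISA
    electropherogram peaks into OTU tables, Bray-Curtis/NMDS/ANOSIM community
    statistics, and a resampling analysis of shared OTUs between samples.
    Includes seeded synthetic-data generators for every input class so the
    full pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
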