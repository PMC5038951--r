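Package: mcfnet
Title: Data-Driven Composite Metabolic Pathways for Cancer Classification
    and Survival Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Overlays ranked gene expression on a genome-scale metabolic
    network to discover composite, non-canonical pathway features: seed
    reporter metabolites are found from differentially expressed reactions,
    heaviest simple-path distances on patient-specific weighted metabolite
    graphs form per-seed feature sets, and an ensemble of per-seed support
    vector machines classifies cancerous versus noncancerous samples.
    Learned pathway definitions transfer to unseen cohorts for survival
    scoring via a cancer/normal pathway-weight ratio, evaluated with
    Kaplan-Meier extremes, log-rank tests and the concordance index.
    Includes loaders for SBML and a JSON model dialect, a synthetic-data
    generator with planted differential paths, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
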