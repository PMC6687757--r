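Package: golgiscreen
Title: Epistatic RNAi Screening of Tether-Dependent Golgi Fragmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for epistatic suppression
    screens of CATCHR-tether-dependent Golgi fragmentation. Generates
    synthetic fluorescence fields with per-cell ground truth, full
    RNAi screen datasets with planted suppressors, messy molecular
    interaction tables and electron-microscopy morphometry tables;
    quantifies per-cell Golgi fragment number and area from image
    stacks (Richardson-Lucy deconvolution, maximum-intensity
    projection, robust intensity segmentation); calls per-siRNA rescue
    strength and per-target suppressor status under a majority hit
    rule; filters and analyses protein-protein interaction networks
    (high-confidence filtering, graph cleaning, neighbourhood
    extraction with localization filters, betweenness centrality,
    seed-to-tether path distances); and summarises EM morphometrics
    into condition tables with fold and percent changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
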