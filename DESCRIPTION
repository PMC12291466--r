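Package: condkit
Title: Population Analysis and Growth Kinetics of Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterizing populations of biomolecular condensate
    droplets measured by holographic video microscopy. Converts per-droplet
    refractive indexes to dense-phase protein volume fractions and
    concentrations via effective-medium theory, fits and discriminates
    droplet growth mechanisms (power-law coalescence with Smoluchowski
    dynamic scaling, Lifshitz-Slyozov-Wagner ripening, self-regulated
    gel-point coagulation), quantifies disequilibrium and run-to-run
    reproducibility with distance correlation and Jensen-Shannon divergence,
    and analyzes subdiffraction structure and dynamics with DBSCAN clustering
    of single-molecule localizations and temporal image correlation maps.
    Includes stochastic simulators (coagulation, mean-field ripening,
    measurement model) so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
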