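Package: methanoflux
Title: Constraint-Based Analysis of Methanotroph Metabolism
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flux balance analysis (FBA) of genome-scale metabolic models of
    polyhydroxybutyrate (PHB) accumulating type II methanotrophs. Provides a
    constraint-based model container with SBML and tab-separated readers and
    writers, a bounded-variable simplex linear-programming engine with
    parsimonious FBA, flux variability analysis, reaction essentiality and
    two-objective Pareto sweeps, the three alternative particulate methane
    monooxygenase electron-donor mechanisms (redox arm, direct coupling,
    uphill electron transfer), scenario pipelines for methane growth yields,
    methane-PHB co-consumption and anoxic PHB oxidation coupled to
    denitrification, metabolic network degree-distribution statistics, and a
    packaged core methanotroph model calibrated to published physiology of
    Methylocystis-like strains.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
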