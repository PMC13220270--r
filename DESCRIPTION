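Package: protonpath
Title: Proton-Channel Detection, Hydration Profiling and Transport Kinetics
    for Membrane Antiporter Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing trans-membrane proton pathways in
    respiratory-chain antiporter modules. Detects membrane-spanning
    channels in sphere-approximated protein structures by a widest-path
    (maximin bottleneck) search on a clearance grid, parameterises the
    channel by arc length, and profiles water occupancy and intra-protein
    electric fields along the channel coordinate from molecular-dynamics
    trajectories with replica aggregation. Also quantifies proteoliposome
    proton-transport spectroscopy: ratiometric pyranine (HPTS) pH traces,
    oxonol VI membrane-potential kinetics with Nernst-based calibration,
    capacitance-based per-liposome proton fluxes, and oxygen-consumption
    assays normalised by protein content and NADH-dehydrogenase activity.
    A synthetic-data module generates channel-bearing pseudo-structures,
    water trajectories with known occupancy, point-charge systems with
    closed-form fields, and assay traces with known parameters, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
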