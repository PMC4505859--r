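Package: pipbind
Title: Coarse-Grained Analysis of Protein Binding to PIP2-Containing Bilayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds coarse-grained protein/bilayer systems with an
    asymmetrically PIP2-enriched leaflet, runs a Brownian-dynamics toy
    simulator of electrostatically driven membrane association, and analyses
    trajectories for residue-level PIP2 contact occupancy, binding
    stoichiometry, lipid contact censuses, radial distribution functions,
    protein orientation, and binding-site pose classification. Includes
    readers and writers for GRO coordinates, multi-frame GRO trajectories,
    PDB structures and tabular topology sidecars, plus an end-to-end
    build/simulate/analyze/report pipeline driven by a YAML configuration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    bio3d,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
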