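Package: colloidkit
Title: Structure-Based Descriptors for Colloidal Protein-Protein Interactions
Version: 0.1.0
Authors@R: person("colloidkit", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating colloidal protein-protein interaction
    propensity from structure-based descriptors. Builds rigid fullerene-shell
    pseudo-proteins carrying protein-like surface charge topologies, computes
    local surface-patch descriptors (local sum of squared charges and local
    sum of charges), net charge, dipole moment, solvent accessible surface
    area (Shrake-Rupley) and spatial-aggregation-propensity (SAP) family
    scores for real protein structures, scans single charge-flip mutations
    for the largest dipole reduction, fits linear solubility models combining
    net charge with one additional descriptor, and extracts contact minima
    from potential-of-mean-force curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
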