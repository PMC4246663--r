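Package: fluxscan
Title: Minimal-Total-Flux Balance Analysis Scans of Compartmented Leaf Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flux balance analysis of a compartmented (cytosol, chloroplast,
    mitochondrion) leaf mesophyll metabolic network under a minimal-total-flux
    objective. Reads stoichiometric models in a ScrumPy-style reaction dialect
    or SBML Level 3 core, converts measured biomass and phloem-sap composition
    into fixed export-transporter constraints with equal-carbon normalisation,
    scans the linear programme across photon flux and the biomass-to-phloem
    output transition, locates the minimal feasible light by bisection, detects
    flux-pattern regions, and computes derived quantities: relative flux
    differences, the Assimilatory Quotient (CO2 fixed per O2 released),
    active-reaction counts, compartment exchange fluxes and nitrogen-source
    shares. Ships a parameterised synthetic core-leaf model generator and an
    exact-rational vertex-enumeration oracle so the whole pipeline is testable
    on desk-scale fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
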