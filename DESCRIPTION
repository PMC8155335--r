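Package: vesibud
Title: Dissipative Particle Dynamics of Nanovesicles with Adsorbing
    Solutes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained dissipative particle dynamics (DPD)
    simulation of lipid nanovesicles exposed to small solutes that
    adsorb onto the outer membrane leaflet, together with the analysis
    stack that turns trajectories into solute coverage, spherical
    stress profiles, bilayer tension, spontaneous curvature, elastic
    moduli, liquid-liquid coexistence (binodal) estimates, and vesicle
    morphology observables such as neck diameter, division and contact
    area. Includes system builders for bulk solutions, slabs, planar
    bilayers and spherical vesicles with prescribed leaflet lipid
    numbers, deflation/inflation and solute-titration protocols, and
    extended-XYZ / LAMMPS-dump trajectory serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
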