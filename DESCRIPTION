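Package: pigmentNet
Title: Pigment Networks and Excitation Energy Transfer Pathways in
    Photosynthetic Supercomplexes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts chlorophyll and carotenoid cofactors from
    macromolecular coordinate files (mmCIF/PDB) of pigment-protein
    supercomplexes and analyses their spatial organisation: membrane
    leaflet assignment from the chlorophyll cloud, contact-graph
    classification of antenna subunits into concentric layers around
    the photosystem core, detection of coupled chlorophyll pairs,
    derivation of inter-subunit excitation energy transfer (EET) steps
    from Mg-Mg distances, and enumeration of antenna-to-core EET
    pathways with their canonical codes. Includes a pigment census and
    stoichiometry report, a seeded synthetic supercomplex generator
    with full ground truth for end-to-end validation, and a packaged
    encoding of the published diatom PSI-FCPI pathway table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    igraph,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StructuralPrediction, Proteomics, Network
RoxygenNote: 7.3.3
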