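Package: glycofel
Title: Puckering Free-Energy Landscapes and Catalytic Observables for
    Glycoside Hydrolases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis layer for QM/MM metadynamics studies of
    glycoside hydrolase catalysis. Computes and inverts Cremer-Pople
    puckering coordinates for six-membered sugar rings and classifies the
    38 canonical ring conformers; reads PLUMED-style HILLS records and
    reconstructs well-tempered metadynamics free-energy surfaces on
    periodic/bounded 2D grids; extracts minimum free-energy paths by the
    global minimax criterion with activation and reaction free energies;
    evaluates proton-transfer and nucleophilic-attack collective variables
    and catalytic distances from PDB structures; computes Shrake-Rupley
    solvent-accessible surface areas and the substrate-positioning index;
    and ships a seeded overdamped-Langevin well-tempered sampler of
    analytic 2D potentials so every stage is testable with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
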