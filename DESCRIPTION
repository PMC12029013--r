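Package: peritraj
Title: Surface-Diffusion and Lipid-Contact Analysis for Peripheral
    Membrane Proteins
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyzes molecular-dynamics trajectories of peripheral
    proteins diffusing on lipid bilayers: membrane insertion depth with
    bimodal mode detection and two-state "skipping" segmentation,
    heme-plane tilt angles with axial circular statistics, protein-lipid
    contact classification with composition-normalized relative lipid
    affinities, and mean-square-displacement estimation of 2D/3D Fickian
    diffusion coefficients. Includes a synthetic trajectory generator
    with exact ground truth (typed anionic membrane, two-state Markov
    skipping motion, prescribed diffusion coefficients and tilt angles)
    so the whole pipeline is testable without simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
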