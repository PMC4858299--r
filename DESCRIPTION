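Package: capstress
Title: Finite-Element Analysis of Cholesterol-Crystal Stress on Atherosclerotic Fibrous Caps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plane-strain finite-element modelling of an idealized atherosclerotic
    coronary cross-section with expanding cholesterol crystals. Builds structured
    meshes of 8-node quadrilaterals from printed plaque morphometrics, solves
    static linear elasticity with polar-orthotropic artery and plaque tissue,
    luminal pressure and crystal eigenstrain loading, and extracts the peak
    circumferential stress (PCS) on the fibrous cap across crystal-placement
    scenarios and expansion, pressure and stiffness sweeps. Also includes
    micro-OCT B-scan morphometry of thin plate-like crystals and a synthetic
    speckle B-scan generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
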