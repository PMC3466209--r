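Package: semfilm
Title: Electron Transport and Image Simulation for Metal-Coated-Film SEM
    of Unstained Biomolecules
Version: 0.3.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models scanning electron microscopy of unstained proteins and
    viruses mounted under a metal-coated silicon-nitride film. Provides a
    single-scattering Monte Carlo simulator for electron transport through
    layered thin films (screened-Rutherford elastic scattering with
    Joy-Luo continuous slowing down), the electrostatic charging arithmetic
    for the irradiated spot on the insulating film, synthetic specimen
    phantoms (rod-shaped virion, star-shaped antibody pentamer, dumbbell
    proteasome, straight edge), a forward micrograph simulator with
    beam-spread blur and Poisson shot noise, and the post-processing chain:
    contrast inversion, Gaussian smoothing, Lucy-Richardson deconvolution
    with compound-Gaussian point spread functions, and edge-based (Reimer)
    resolution estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
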