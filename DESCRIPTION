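Package: osteosim
Title: Bone Remodeling and Biodegradable Implant Osteogenesis Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Coupled simulation of bone functional adaptation (Wolff-law
    density remodeling by mass-constrained strain-energy minimization) and
    biodegradable implant degradation on two-dimensional plane-stress finite
    element domains. Provides parametric proximal-femur and rat-metaphysis
    stand-in meshes, a bilinear quadrilateral elasticity solver, an
    optimality-criteria density update, implant degradation laws, and
    osteogenesis metrics (bone-attributable modulus, new-bone fraction,
    refilled defect area) with tidy per-day traces and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
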