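Package: valvegen
Title: Automatic Generation and Evaluation of Heart-Valve Leaflet Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Parametric construction of bioprosthetic heart-valve leaflet
    geometries, quasi-static explicit membrane finite-element simulation of
    the systolic opening phase under a transvalvular pressure load, and
    quantitative evaluation of candidate designs by von Mises stress
    statistics, degree of opening and a combined loss index.  Includes
    averaging of multi-sample uniaxial tensile curves into a cubic
    stress-strain law, a synthetic tensile-curve generator, batch
    design-space exploration over stated parameter ranges with filtering,
    quartile summaries and per-size selection of optimal designs, STL, VTK
    and Abaqus-INP export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    parallel,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
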