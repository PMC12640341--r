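Package: colonycap
Title: Continuum Spherical-Cap Model of Contact-Inhibited Cell Colony Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic continuum simulator for cell colony growth on a flat
    surface under variable contact inhibition and directional growth anisotropy.
    Two coupled ordinary differential equations track the basal-layer and total
    cell numbers; at every evaluation the colony geometry is closed by a
    spherical-cap model (iterative height inversion, reduced sub-caps for the
    perimeter/internal cell partition), yielding kinetics of colony radius,
    height, curvature, composite shape parameter and receding contact angle.
    Includes the three-anisotropy-regime by five-inhibition-level reference
    parameter grid, midsection profile extraction, tidy trajectory output and
    ggplot2 visualisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
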