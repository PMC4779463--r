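Package: porotrab
Title: Poroelastic Trabecular Remodelling and Strain-Based Adaptation Laws
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Mechanistic simulation of surface remodelling of a single trabecula
    driven by interstitial fluid velocity, and the distillation of those results
    into phenomenological strain-based adaptation laws for beam-element models of
    trabecular bone. Implements a transient two-dimensional plane-strain Biot
    poroelasticity finite-element solver with equal-order quadrilateral elements,
    a spline-bounded adaptive geometry whose lateral surfaces move in response to
    Darcy flux magnitudes, a quadratic Timoshenko beam twin with end rotational
    springs and elastic end plates, an equivalent-beam reduction of remodelled
    geometries (reorientation and cross-section ratio), and regression fits of the
    cubic reorientation law and the slope/intercept cross-section law, with a
    scripted study driver for full load sweeps and a validation scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
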